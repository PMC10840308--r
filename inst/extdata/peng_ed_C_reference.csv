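# Frozen reference curve: electron scattering factor of carbon evaluated
# from the bundled 5-Gaussian coefficients (peng_ed_5g.csv); used as a
# self-consistency regression fixture for the Gaussian evaluator.
s,f
0.0,2.50880000000
0.1,2.13793557851
0.2,1.45960749653
0.3,0.93257251117
0.4,0.60576821720
0.5,0.41358297592
0.6,0.29682846754
0.7,0.22287992336
0.8,0.17458834019
0.9,0.14150023186
1.0,0.11739269284
1.1,0.09896480667
1.2,0.08453604207
1.3,0.07313556178
1.4,0.06406451534
1.5,0.05675194239
1.6,0.05072903059
1.7,0.04562949060
1.8,0.04118484723
1.9,0.03721083459
2.0,0.03358905902
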