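# Four-Gaussian-plus-constant X-ray scattering factor coefficients
# f(s) = sum_i a_i exp(-b_i s^2) + c, s = sin(theta)/lambda in 1/Angstrom.
# Transcribed from the conventional independent-atom-model tabulation
# (International Tables for Crystallography Vol. C, analytical
# approximations to the Cromer-Mann scattering factors). a5/b5 unused.
species,a1,a2,a3,a4,a5,b1,b2,b3,b4,b5,c
H,0.489918,0.262003,0.196767,0.049879,0,20.6593,7.74039,49.5519,2.20159,0,0.001305
C,2.31000,1.02000,1.58860,0.865000,0,20.8439,10.2075,0.568700,51.6512,0,0.215600
N,12.2126,3.13220,2.01250,1.16630,0,0.005700,9.89330,28.9975,0.582600,0,-11.529
O,3.04850,2.28680,1.54630,0.867000,0,13.2771,5.70110,0.323900,32.9089,0,0.250800
Ca,8.62660,7.38730,1.58990,1.02110,0,10.4421,0.659900,85.7484,178.437,0,1.37510
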