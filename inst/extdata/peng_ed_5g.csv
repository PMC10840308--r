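# Gaussian electron-diffraction scattering factor coefficients,
# f_e(s) = sum_i a_i exp(-b_i s^2), s = sin(theta)/lambda in 1/Angstrom,
# values in Angstrom; no constant term. Five-term parameterization after
# Peng's kinematic tables (as reproduced in International Tables Vol. C,
# electron scattering section). Only species whose f_e(0) could be verified
# against the accepted values (H 0.529, C 2.509, O 1.983 A) are bundled.
species,a1,a2,a3,a4,a5,b1,b2,b3,b4,b5,c
H,0.0349,0.1201,0.1970,0.0573,0.1195,0.5347,3.5867,12.3471,18.9525,38.6269,0
C,0.0893,0.2563,0.7570,1.0487,0.3575,0.2465,1.7100,6.4094,18.6113,50.2523,0
O,0.0974,0.2921,0.6910,0.6990,0.2039,0.2067,1.3815,4.6943,12.7105,32.4726,0
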