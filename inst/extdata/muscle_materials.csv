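# Muscle constitutive parameters, one row per modeled group.
# Units: N-mm-MPa-s.
#   G         matrix shear modulus (MPa)
#   K         matrix bulk modulus (MPa); 1000 x G (nearly incompressible)
#   sigma0    maximum tetanic stress (MPa), common to all groups
#   A         passive (PE) quadratic constant, dimensionless
#   c_ce_ref  sarcomere-derived active parameter (sarcomere length / 2.8 um)
#   c_ce1     concentric active parameter (shortening, epsilon < 0)
#   c_ce2     eccentric active parameter (lengthening, epsilon > 0)
# LTpTh shares the LTpL row values.
group,G,K,sigma0,A,c_ce_ref,c_ce1,c_ce2
MF,0.001642,1.642,0.46,4.0,0.811,0.706,0.465
LTpL,0.001642,1.642,0.46,4.0,0.825,0.718,0.473
LTpTh,0.001642,1.642,0.46,4.0,0.825,0.718,0.473
ILpL,0.001642,1.642,0.46,4.0,0.846,0.737,0.485
PS,0.001642,1.642,0.46,4.0,1.111,0.967,0.637
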