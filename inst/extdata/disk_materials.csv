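# Intervertebral disk tissue parameters for the 1D poroelastic column.
# Units: MPa, mm^4/(N s).
#   G     shear modulus
#   K     bulk modulus (drained)
#   e0    initial void ratio
#   k0    initial permeability
#   M     strain-dependent permeability exponent
# Strain-dependent permeability:
#   k = k0 * (e (1 + e0) / (e0 (1 + e)))^2 * exp(M ((1 + e)/(1 + e0) - 1))
# normalized so that k(e0) = k0.
tissue,G,K,e0,k0,M
AF,0.95,0.37,3.0,0.0002,8.5
NP,0.47,0.16,4.9,0.0009,8.5
CEP,8.55,10.10,4.0,0.0025,8.5
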