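service,cropland,forest,grassland,wetland,waterbody,desert
food production,1.00,0.33,0.43,0.36,0.53,0.02
raw material production,0.39,2.98,0.36,0.24,0.35,0.04
gas regulation,0.72,4.32,1.50,2.41,0.51,0.06
climate regulation,0.97,4.07,1.56,13.55,2.06,0.13
hydrology regulation,0.77,4.09,1.52,13.44,18.77,0.07
waste treatment,1.39,1.72,1.32,14.40,14.85,0.26
soil conservation,1.47,4.02,2.24,1.99,0.41,0.17
biodiversity maintenance,1.02,4.51,1.87,3.69,3.43,0.40
aesthetic landscape provision,0.17,2.08,0.87,4.69,4.44,0.24
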