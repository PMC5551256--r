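from,cropland,forestland,grassland,wetland,waterbody,construction,unused
cropland,514.51,0.14,130.72,9.82,1.06,11.97,17.30
forestland,0.15,492.14,266.35,19.88,0.00,0.02,3.70
grassland,384.13,507.59,34705.90,1173.80,13.23,20.34,2319.89
wetland,0.22,9.24,1009.59,1959.90,1.74,1.17,71.13
waterbody,0.01,0.14,47.23,25.94,4287.87,0.05,22.64
construction,2.63,0.00,1.14,0.08,0.00,3.60,0.00
unused,11.35,15.43,2585.72,303.90,11.35,0.68,4871.10
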