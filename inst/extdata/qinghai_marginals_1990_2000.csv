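class,area_1990_km2,area_2000_km2
cropland,685.52,913.00
forestland,782.24,1024.68
grassland,39124.88,38746.64
wetland,3052.98,3493.31
waterbody,4383.89,4315.26
construction,7.45,37.85
unused,7799.54,7305.76
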