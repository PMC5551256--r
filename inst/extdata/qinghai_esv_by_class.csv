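year,cropland,forestland,grassland,wetland,waterbody,construction
1990,4.37,17.75,368.35,134.90,160.39,8.75
2000,5.82,23.25,364.79,154.35,157.88,8.19
2010,4.72,26.68,371.05,134.29,158.96,7.89
2020,3.93,28.09,375.41,122.50,159.07,7.72
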