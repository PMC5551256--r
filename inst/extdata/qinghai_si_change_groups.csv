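comparison,change,n_towns,area_1e4_km2
1990-2000_vs_2000-2010,decrease,23,39.07
1990-2000_vs_2000-2010,increase,14,16.68
2000-2010_vs_2010-2020,decrease,9,22.20
2000-2010_vs_2010-2020,increase,28,33.56
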