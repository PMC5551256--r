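crop,sowing_area_hm2,price_yuan_per_t,yield_t_per_hm2
wheat,21500,2100,3.1
coarse cereal,9800,1650,2.2
tuber,6400,1400,3.8
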