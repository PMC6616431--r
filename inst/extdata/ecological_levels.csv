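level_key,ecological_level
farmland,0.11
forestland,0.245
shrub_land,0.147
grassland_high,0.125
grassland_mid,0.063
grassland_low,0.018
water_land,0.282
unused_land,0.01
built_up,0.01
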