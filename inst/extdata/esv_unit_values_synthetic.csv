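class,unit_value_yuan_ha
farmland,6100
forestland,19300
grassland,6400
water_land,40700
built_up,0
unused,400
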