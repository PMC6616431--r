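class,resilience
farmland,0.4
forestland,0.9
grassland,0.6
water_land,0.8
built_up,0.05
unused,0.2
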