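technique,endpoint_h,gp_mL_per_g
automated,6,80
automated,12,111
automated,24,145
automated,48,185
manual,6,75
manual,12,104
manual,24,130
manual,48,166
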