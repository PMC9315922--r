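category,crc,eric
zero_mut,609,650
s_only,34,31
r_only,114,122
s_plus_r,933,1105
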