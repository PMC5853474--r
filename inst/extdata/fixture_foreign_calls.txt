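sp2_g0001
sp2_g0002
sp2_g0003
sp2_g0005
sp2_g0009
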