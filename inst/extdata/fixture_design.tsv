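sample	condition
young_1	young
young_2	young
young_3	young
expanded_1	expanded
expanded_2	expanded
expanded_3	expanded
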