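marker,known_value,known_unit,observed_position
chymotrypsinogen,2.58,S,15.9
albumin,4.22,S,14.6
aldolase,7.4,S,12.1
catalase,11.4,S,8.9
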