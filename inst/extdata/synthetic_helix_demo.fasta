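>demo_amphipathic_helix synthetic idealized 18-mer
LKKLLKKLLKLLKKLLKK
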