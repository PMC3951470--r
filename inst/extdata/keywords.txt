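interact
interacts
interacted
interacting
interaction
regulate
regulates
regulated
regulating
regulation
modulate
modulates
modulated
modulating
modulation
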