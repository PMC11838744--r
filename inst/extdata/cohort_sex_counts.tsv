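cohort	onset	male	female
multiplex	early	131	92
multiplex	late	224	148
simplex	early	131	92
simplex	late	224	148
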