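3
Properties=species:S:1:pos:R:3:field:R:3 energies="-0.5 1.25"
O 0.0 0.0 0.1173 0.0 0.0 0.0005
H 0.0 0.7572 -0.4692 0.0005 0.0 0.0
H 0.0 -0.7572 -0.4692 0.001 -0.002 0.0
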