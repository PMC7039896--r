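# synthetic electrode spec for tests (shorter custom array)
name: CUSTOM20
total_length_mm: 20.9
c1_to_stopper_mm: 19.7
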