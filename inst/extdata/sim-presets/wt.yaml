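# Wild-type condition: per-step cytoneme formation probability 1/30
pFilo: 0.033333333333333333
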