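# Enhanced receptor activity: cytoneme number scaled by 1.61
# pFilo = 1.61 * 1/30
pFilo: 0.0537
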