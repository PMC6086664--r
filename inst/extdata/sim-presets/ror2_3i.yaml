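# Kinase-dead receptor: cytoneme number scaled by 0.338
# pFilo = 0.338 * 1/30
pFilo: 0.0113
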