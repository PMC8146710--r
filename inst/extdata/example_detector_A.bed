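chr	49999	106000	regionA1
chr	200000	231000	regionA2
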