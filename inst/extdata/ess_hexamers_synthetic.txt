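TAGGGT
GTAGGG
TTAGGG
GGGTGG
TAGACT
CTAGAC
TTTAGG
AGGGTA
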