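# two seed genes from the planted pair
AT03G09601
AT03G04189
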