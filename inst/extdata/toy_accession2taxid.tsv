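NC_CHK_1	4
NC_TRK_1	6
NC_PIG_1	9
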