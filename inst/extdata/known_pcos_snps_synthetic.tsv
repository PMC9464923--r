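SNP	CHR	BP
rs804274	8	11625205
rs7929660	11	30339461
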