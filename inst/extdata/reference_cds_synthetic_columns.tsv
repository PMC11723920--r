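cd_id	cage1	cage2	cage3	clasp1	clasp2
hp1_like_synthetic	2	23	26	14	28
pc_like_synthetic	3	24	27	14	28
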