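>hp1_like_synthetic H3K9me-type exemplar chromodomain (synthetic; intact Y/W/Y cage, polar clasp, acidic)
EYVVEKVLDRRVVNGKVEYLLKWKGYPETENTWEPEDNLDCQDLIQEYEASRKDE
>pc_like_synthetic H3K27me-type exemplar chromodomain (synthetic; intact Y/W/W cage, nonpolar clasp, basic)
GSYAAEKIIQKRVLKGKVEYLVKWKGWAQKYSTWEPEVNILDSRLLAAYEQKERP
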