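reference_c,replicate,reading_c
35,1,35.0213962502185
35,2,35.0479658134571
35,3,35.0087828704974
36,1,36.0443858507495
36,2,35.9637162079481
36,3,36.0122674029525
37,1,36.9136154811855
37,2,37.0489624266692
37,3,36.9635883087453
38,1,37.8705757993318
38,2,37.9254230954571
38,3,38.0921550362006
39,1,39.0750054350401
39,2,38.7491445984108
39,3,38.6959065904656
40,1,40.0000265800543
40,2,39.9605981005771
40,3,39.8254972339222
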