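"cl","lower","upper"
600,156.625325283695,333.768757804855
550,144.677549709382,322.170360870565
500,134.285412806151,311.692810001241
450,123.665024178315,300.918848011757
400,112.406214250462,290.386377586878
350,96.9338936807485,278.788014475793
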