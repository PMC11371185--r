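"genotype","cell_id","stage","raw_intensity","background"
"AACC_wt","cell01","zygotene_early_pachytene",1191.6,142.1
"AACC_wt","cell02","zygotene_early_pachytene",1048.5,156.8
"AACC_wt","cell03","zygotene_early_pachytene",1236.8,130.6
"AACC_wt","cell04","zygotene_early_pachytene",1546.7,148
"AACC_wt","cell05","zygotene_early_pachytene",1272.5,121.4
"AACC_wt","cell06","zygotene_early_pachytene",1294.5,165.5
"AACC_wt","cell07","zygotene_early_pachytene",1246.3,143.8
"AACC_wt","cell08","zygotene_early_pachytene",1080.4,166.1
"aaCc","cell09","zygotene_early_pachytene",497,143.1
"aaCc","cell10","zygotene_early_pachytene",507.7,157.8
"aaCc","cell11","zygotene_early_pachytene",511.5,150.7
"aaCc","cell12","zygotene_early_pachytene",598.2,135.3
"aaCc","cell13","zygotene_early_pachytene",542.7,177.1
"aaCc","cell14","zygotene_early_pachytene",584.7,169.2
"aaCc","cell15","zygotene_early_pachytene",381.3,135.2
"aaCc","cell16","zygotene_early_pachytene",324.2,157.7
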