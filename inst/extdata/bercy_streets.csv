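street,n_tree_bases,smallest_distance_m,nearest_green_space,pct_LM,pct_LMR,pct_PRM
BARO,62,166,railways,53,13,33
BATA,31,63,railways,40,0,60
BERC,126,33,railways,47,27,27
BERY,99,148,river,40,13,47
CHAR,144,41,railways,53,13,33
DAUM,186,7,footpath,27,7,67
KESS,69,3,park,33,13,53
LACH,31,13,railways,27,0,73
MONT,52,125,footpath,40,13,47
POMM,39,17,park,27,0,73
RAPE,97,64,river,47,13,40
RBER,136,88,railways,40,7,53
REUI,145,224,footpath,60,7,33
TAIN,62,38,railways,20,7,73
TERR,45,177,river,47,7,47
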