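# Published per-comparison DEG counts for domestic animals versus their wild
# counterparts (summary form: one row per species-pair x tissue, n_deg column).
domestic	wild	tissue	n_deg	ref
tame rats	aggressive rats	hypothalamus	46	B212
tame rats	aggressive rats	hippocampus	42	B99
tame rats	aggressive rats	midbrain tegmentum	31	B213
tame rats	aggressive rats	periaqueductal gray matter	39	B214
tame rats	aggressive rats	frontal cortex	20	B215
guinea pigs	cavy	frontal cortex	883	B215
domestic rabbits	wild rabbits	frontal cortex	17	B215
domestic rabbits	wild rabbits	parietal-temporal cortex	216	B216
domestic rabbits	wild rabbits	amygdala	118	B216
domestic rabbits	wild rabbits	hypothalamus	43	B216
domestic rabbits	wild rabbits	hippocampus	100	B216
dogs	wolves	blood	450	B217
dogs	wolves	frontal cortex	13	B215
tame foxes	aggressive foxes	pituitary	327	B218
pigs	boars	frontal cortex	30	B215
pigs	boars	frontal cortex	34	B219
pigs	boars	pituitary	22	B220
domestic chicken	wild chicken	pituitary	474	B221
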