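# Synthetic concordance fixture: 26 reconstructed animal DEG records whose
# per-process worsen/relief margins match the published concordance matrix
# (10/16, 14/12, 2/24). These are NOT the study data; gene symbols HUB01..26
# and the homology map are constructed for testing only.

domestic	wild	tissue	gene	direction	ref
dogs	wolves	blood	hub01	up_in_domestic	synthetic
pigs	boars	frontal cortex	hub02	up_in_domestic	synthetic
tame rats	aggressive rats	hypothalamus	hub03	up_in_domestic	synthetic
domestic rabbits	wild rabbits	pituitary	hub04	up_in_domestic	synthetic
tame foxes	aggressive foxes	hippocampus	hub05	up_in_domestic	synthetic
guinea pigs	cavy	blood	hub06	up_in_domestic	synthetic
domestic chicken	wild chicken	frontal cortex	hub07	up_in_domestic	synthetic
dogs	wolves	hypothalamus	hub08	up_in_domestic	synthetic
pigs	boars	pituitary	hub09	up_in_domestic	synthetic
tame rats	aggressive rats	hippocampus	hub10	up_in_domestic	synthetic
domestic rabbits	wild rabbits	blood	hub11	up_in_domestic	synthetic
tame foxes	aggressive foxes	frontal cortex	hub12	up_in_domestic	synthetic
guinea pigs	cavy	hypothalamus	hub13	up_in_domestic	synthetic
domestic chicken	wild chicken	pituitary	hub14	up_in_domestic	synthetic
dogs	wolves	hippocampus	hub15	up_in_domestic	synthetic
pigs	boars	blood	hub16	up_in_domestic	synthetic
tame rats	aggressive rats	frontal cortex	hub17	up_in_domestic	synthetic
domestic rabbits	wild rabbits	hypothalamus	hub18	up_in_domestic	synthetic
tame foxes	aggressive foxes	pituitary	hub19	up_in_domestic	synthetic
guinea pigs	cavy	hippocampus	hub20	up_in_domestic	synthetic
domestic chicken	wild chicken	blood	hub21	up_in_domestic	synthetic
dogs	wolves	frontal cortex	hub22	up_in_domestic	synthetic
pigs	boars	hypothalamus	hub23	up_in_domestic	synthetic
tame rats	aggressive rats	pituitary	hub24	up_in_domestic	synthetic
domestic rabbits	wild rabbits	hippocampus	hub25	up_in_domestic	synthetic
tame foxes	aggressive foxes	blood	hub26	up_in_domestic	synthetic
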