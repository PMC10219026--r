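# Synthetic animal-to-human homology map for the concordance fixture.
animal_gene	human_gene
hub01	HUB01
hub02	HUB02
hub03	HUB03
hub04	HUB04
hub05	HUB05
hub06	HUB06
hub07	HUB07
hub08	HUB08
hub09	HUB09
hub10	HUB10
hub11	HUB11
hub12	HUB12
hub13	HUB13
hub14	HUB14
hub15	HUB15
hub16	HUB16
hub17	HUB17
hub18	HUB18
hub19	HUB19
hub20	HUB20
hub21	HUB21
hub22	HUB22
hub23	HUB23
hub24	HUB24
hub25	HUB25
hub26	HUB26
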