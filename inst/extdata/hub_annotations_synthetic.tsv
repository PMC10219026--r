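# Synthetic annotation fixture (health-effect maps per process, in the
# order atherogenesis,atherosclerosis,atheroprotection). CRP and SERPINF1
# rows encode the described biology of their protein products; HUB01..26
# are constructed genes whose effect maps realize the published concordance
# margins. PAI ranks here are placeholders for testing.
gene	atherogenesis	atherosclerosis	atheroprotection	pai	effect_under	effect_over
CRP	1	1	1	4	relief,relief,relief	worsen,worsen,worsen
SERPINF1	1	1	1	4	relief,relief,relief	worsen,worsen,worsen
HUB01	1	1	1	3	relief,relief,relief	worsen,worsen,worsen
HUB02	1	1	1	4	relief,relief,relief	worsen,worsen,worsen
HUB03	1	1	1	5	relief,relief,worsen	worsen,worsen,relief
HUB04	1	1	1	6	relief,relief,worsen	worsen,worsen,relief
HUB05	1	1	1	3	relief,relief,worsen	worsen,worsen,relief
HUB06	1	1	1	4	relief,relief,worsen	worsen,worsen,relief
HUB07	1	1	1	5	relief,relief,worsen	worsen,worsen,relief
HUB08	1	1	1	6	relief,relief,worsen	worsen,worsen,relief
HUB09	1	1	1	3	relief,relief,worsen	worsen,worsen,relief
HUB10	1	1	1	4	relief,relief,worsen	worsen,worsen,relief
HUB11	1	1	1	5	worsen,relief,worsen	relief,worsen,relief
HUB12	1	1	1	6	worsen,relief,worsen	relief,worsen,relief
HUB13	1	1	1	3	worsen,relief,worsen	relief,worsen,relief
HUB14	1	1	1	4	worsen,relief,worsen	relief,worsen,relief
HUB15	1	1	1	5	worsen,worsen,worsen	relief,relief,relief
HUB16	1	1	1	6	worsen,worsen,worsen	relief,relief,relief
HUB17	1	1	1	3	worsen,worsen,worsen	relief,relief,relief
HUB18	1	1	1	4	worsen,worsen,worsen	relief,relief,relief
HUB19	1	1	1	5	worsen,worsen,worsen	relief,relief,relief
HUB20	1	1	1	6	worsen,worsen,worsen	relief,relief,relief
HUB21	1	1	1	3	worsen,worsen,worsen	relief,relief,relief
HUB22	1	1	1	4	worsen,worsen,worsen	relief,relief,relief
HUB23	1	1	1	5	worsen,worsen,worsen	relief,relief,relief
HUB24	1	1	1	6	worsen,worsen,worsen	relief,relief,relief
HUB25	1	1	1	3	worsen,worsen,worsen	relief,relief,relief
HUB26	1	1	1	4	worsen,worsen,worsen	relief,relief,relief
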