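# 15-position TATA-box position frequency matrix, transcribed strand.
# Provenance: synthetic compilation built from the canonical TATAWAWR core
# consensus (positions 3-10) with weakly G/C-preferring flanks; NOT taken
# from any single published collection. Scores are log-odds vs a uniform
# background, computed at load time from these frequencies.
position	A	C	G	T
1	0.20	0.28	0.30	0.22
2	0.22	0.25	0.28	0.25
3	0.05	0.05	0.05	0.85
4	0.90	0.02	0.03	0.05
5	0.15	0.02	0.03	0.80
6	0.90	0.02	0.03	0.05
7	0.65	0.03	0.02	0.30
8	0.85	0.03	0.02	0.10
9	0.55	0.05	0.10	0.30
10	0.45	0.10	0.35	0.10
11	0.25	0.20	0.35	0.20
12	0.22	0.25	0.33	0.20
13	0.20	0.28	0.32	0.20
14	0.22	0.26	0.30	0.22
15	0.24	0.26	0.28	0.22
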