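# Dinucleotide step properties used by the three-stage TBP binding model.
# slide: nonspecific TBP-DNA affinity weight during one-dimensional sliding,
#   taken as the A/T (weak base-pair) content of the step in [0, 1]; TBP
#   contacts the minor groove, which is most accessible in A/T-rich DNA.
# bend: relative minor-groove bendability in [0, 1]; synthetic scale encoding
#   the published flexibility ordering of dinucleotide steps
#   (pyrimidine-purine steps TA > CA/TG > CG most flexible; G/C-rich and
#   purine-pyrimidine steps stiffest), not copied from any single dataset.
step	slide	bend
AA	1.0	0.55
AC	0.5	0.45
AG	0.5	0.30
AT	1.0	0.50
CA	0.5	0.80
CC	0.0	0.30
CG	0.0	0.65
CT	0.5	0.30
GA	0.5	0.40
GC	0.0	0.20
GG	0.0	0.30
GT	0.5	0.45
TA	1.0	1.00
TC	0.5	0.40
TG	0.5	0.80
TT	1.0	0.55
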