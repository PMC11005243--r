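# Default immune checkpoint gene panel (26 genes, 6 anchors).
# The six anchor genes (PD-1, PDL-1, CTLA4, CD28, CD80, CD86) are the
# checkpoints directly engaged by anti-PD-1 / anti-CTLA-4 therapy; every
# candidate pair feature must contain at least one of them.
# The 20 non-anchor members are a representative curated set of
# costimulatory / co-inhibitory checkpoint genes assembled for this
# package's defaults; the panel is a configuration input and users
# analysing real cohorts should supply their own file restricted to the
# genes actually measured across their datasets.
gene_id	is_anchor
PD-1	1
PDL-1	1
CTLA4	1
CD28	1
CD80	1
CD86	1
CD27	0
CD40	0
CD40L	0
CD47	0
CD137	0
CD137L	0
CD200	0
CD200R1	0
CD276	0
BTLA	0
TNFRSF14	0
TNFRSF18	0
OX40	0
OX40L	0
ICOS	0
ICOSL	0
IL2RB	0
LAG3	0
TIM-3	0
PDL-2	0
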