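module	n_genes	n_epistatic	n_hubs	n_hub_epistatic
turquoise	1534	184	152	46
blue	919	49	92	12
brown	373	12	37	1
green	260	80	26	20
black	160	18	16	11
red	248	2	25	0
yellow	350	61	35	27
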