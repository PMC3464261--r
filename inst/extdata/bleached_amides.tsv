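# Backbone amides bleached by Cu2+ at 1:1 stoichiometry, and side-chain
# N-H groups affected at the same ratio. Two backbone lists ship because
# the published body text omits GLN 52 while the figure caption includes
# it; neither is authoritative.
# columns: list_id, resno, resname, atom
list	resno	resname	atom
backbone_text	20	HIS	H
backbone_text	21	CYS	H
backbone_text	22	ARG	H
backbone_text	24	TYR	H
backbone_text	43	GLU	H
backbone_text	45	HIS	H
backbone_text	47	SER	H
backbone_text	48	GLU	H
backbone_text	49	CYS	H
backbone_caption	20	HIS	H
backbone_caption	21	CYS	H
backbone_caption	22	ARG	H
backbone_caption	24	TYR	H
backbone_caption	43	GLU	H
backbone_caption	45	HIS	H
backbone_caption	47	SER	H
backbone_caption	48	GLU	H
backbone_caption	49	CYS	H
backbone_caption	52	GLN	H
sidechain	11	GLN	HE2
sidechain	13	GLN	HE2
sidechain	28	GLN	HE2
sidechain	83	GLN	HE2
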