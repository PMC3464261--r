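name	sequence	rule_set	sites
tetraA	AAAA	pepsin_pH1.3
tetraA	AAAA	pepsin_pH>2
ggfg	GGFG	pepsin_pH1.3
ggfg	GGFG	pepsin_pH>2
ggpf	GGPFAAL	pepsin_pH1.3	3
ggpf	GGPFAAL	pepsin_pH>2	3
mixed1	MKVFLAWPYHRLLFAEG	pepsin_pH1.3	3,5,14
mixed1	MKVFLAWPYHRLLFAEG	pepsin_pH>2	3,5,7,8,14
mixed2	ACDEFGHIKLMNPQRSTVWY	pepsin_pH1.3	4,5,10
mixed2	ACDEFGHIKLMNPQRSTVWY	pepsin_pH>2	4,5,10,18
helix_fl	AAAAFLAAAA	pepsin_pH1.3	4,5,6
helix_fl	AAAAFLAAAA	pepsin_pH>2	4,5,6
synthetic_2s	MAKLTILVALALFLLAAHASARQQWELQGDRRCQSQLERANLRPCEQHLMQKIQRDEDSYERDPYSPSQDPYSPSQDPDRRDPYSPSPYDRRGAGSSQHQERCCNELNEFENNQ	pepsin_pH1.3	3,4,6,7,9,10,11,12,13,14,15,26,27,36,37,48,49,106,107,109,110
synthetic_2s	MAKLTILVALALFLLAAHASARQQWELQGDRRCQSQLERANLRPCEQHLMQKIQRDEDSYERDPYSPSQDPYSPSQDPDRRDPYSPSPYDRRGAGSSQHQERCCNELNEFENNQ	pepsin_pH>2	3,4,6,7,9,10,11,12,13,14,15,25,26,27,36,37,48,49,59,60,71,88,106,107,109,110
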