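sequence	protein	percent_normalized_volume
DPSSGLGVTKQDLGPVPM	CD74	1.9
SLDRNLPSDSQDLGQHGLEEDFML	Serglycin	1.9
SGFHPSDIEVDLLK	Beta-2-microglobulin	1.8
LPKPPKPVSKMRMATPLLMQALP	CD74	1.5
YRYDLASGATEQLPLT	Sortilin-related receptor	1.3
LPSADEIYDCKVEHWG	MHC class II DQA	1.2
QDLGQHGLEEDFML	Serglycin	1.1
HPSDIEVDLLK	Beta-2-microglobulin	1.1
YYTEFTPTEKDEY	Beta-2-microglobulin	1.0
GFHPSDIEVDLLK	Beta-2-microglobulin	1.0
LPSDSQDLGQHGLEEDFML	Serglycin	1.0
QDLGQHGLEEDFM	Serglycin	1.0
YYTEFTPTEKDE	Beta-2-microglobulin	1.0
YLLYYTEFTPTEKDEY	Beta-2-microglobulin	1.0
YLLYYTEFTPTEKDE	Beta-2-microglobulin	0.9
LPSTEDVYDCRVEHWG	MHC class II DRA	0.9
IDNKGIDSDASYPYK	Cathepsin S	0.9
VKTLTGKTITLEVEPSDT	Ubiquitin	0.8
PSDSQDLGQHGLEEDFML	Serglycin	0.8
GVTKQDLGPVPM	CD74	0.8
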