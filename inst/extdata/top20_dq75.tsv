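sequence	protein	percent_normalized_volume
TPLLMQALPMGALPQ	CD74	2.5
ASFEAQGALANIAVDKA	MHC class II DRA	1.7
NPGGYVAYSKAATVTGKL	Transferrin receptor	1.7
TPLLMQALPMGALPQGP	CD74	1.5
NPGGYVAYSKAATVTG	Transferrin receptor	1.5
VPVPQFGGGDPADIIHD	Integral membrane protein 2C	1.4
TPLLMQALPMGALPQGPM	CD74	1.4
VPVPQFGGGDPADIIHDF	Integral membrane protein 2C	1.3
NPGGYVAYSKAATVTGK	Transferrin receptor	1.3
IPELNKVARAAAEVAGQF	Transferrin receptor	1.3
ASFEAQGALANIAVDK	MHC class II DRA	1.1
LPKPPKPVSKMRMATPLLMQALP	CD74	1.1
VDNALQSGNSQESVTEQ	Ig kappa chain C region	0.8
SFEAQGALANIAVDKA	MHC class II DRA	0.7
IEKVEHSDLSFSKDWS	Beta-2-microglobulin	0.7
ATPLLMQALPMGALPQGPM	CD74	0.7
ATPLLMQALPMGALPQGP	CD74	0.7
IPELNKVARAAAEVAG	Transferrin receptor	0.6
LMQALPMGALPQGP	CD74	0.6
IEKVEHSDLSFSKD	Beta-2-microglobulin	0.6
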