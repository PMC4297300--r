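sequence	protein	percent_normalized_volume
LPKPPKPVSKMRMATPLLMQALP	CD74	9.2
PKPPKPVSKMRMATPLLMQALP	CD74	5.5
RMATPLLMQALPMGALPQ	CD74	5.5
MATPLLMQALPMGALPQ	CD74	3.4
RMATPLLMQALPMGALP	CD74	2.7
KPPKPVSKMRMATPLLMQALPM	CD74	2.6
EPRAPWIEQEGPEYWDRN	MHC class I	2.5
MATPLLMQALPMGALP	CD74	2.3
KMRMATPLLMQALPMGALPQ	CD74	2.3
EPRAPWIEQEGPEYWDQE	MHC class I	2.1
MRMATPLLMQALPMGALPQ	CD74	2.0
MATPLLMQALPM	CD74	1.8
RMATPLLMQALPM	CD74	1.7
KPPKPVSKMRMATPLLMQALP	CD74	1.5
RMATPLLMQALPMGAL	CD74	1.5
MATPLLMQALPMGAL	CD74	1.5
LPKPPKPVSKMRMATPLLMQALPM	CD74	1.1
ATPLLMQALPMGALPQ	CD74	1.0
SLDRNLPSDSQDLGQHGLEEDFML	Serglycin	0.9
PSDSQDLGQHGLEEDFML	Serglycin	0.9
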