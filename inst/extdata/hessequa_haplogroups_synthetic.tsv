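individual_id	system	haplogroup
HES001	mtDNA	L0d1b
HES002	mtDNA	L0d1b
HES003	mtDNA	L0d1b
HES004	mtDNA	L0d1b
HES005	mtDNA	L0d1b
HES006	mtDNA	L0d1b
HES007	mtDNA	L0d1b
HES008	mtDNA	L0d1b
HES009	mtDNA	L0d1b
HES010	mtDNA	L0d1b
HES011	mtDNA	L0d1b
HES012	mtDNA	L0d1b
HES013	mtDNA	L0d1b
HES014	mtDNA	L0d1b
HES015	mtDNA	L0d1b
HES016	mtDNA	L0d1b
HES017	mtDNA	L0d1b
HES018	mtDNA	L0d1b
HES019	mtDNA	L0d1b
HES020	mtDNA	L0d1b
HES021	mtDNA	L0d1b
HES022	mtDNA	L0d1b
HES023	mtDNA	L0d1b
HES024	mtDNA	L0d1b
HES025	mtDNA	L0d1b
HES026	mtDNA	L0d1b
HES027	mtDNA	L0d1b
HES028	mtDNA	L0d1b
HES029	mtDNA	L0d1b
HES030	mtDNA	L0d1b
HES031	mtDNA	L0d1b
HES032	mtDNA	L0d1b
HES033	mtDNA	L0d1b
HES034	mtDNA	L0d1b
HES035	mtDNA	L0d1b
HES036	mtDNA	L0d1b
HES037	mtDNA	L0d2a
HES038	mtDNA	L0d2a
HES039	mtDNA	L0d2a
HES040	mtDNA	L0d2a
HES041	mtDNA	L0d2a
HES042	mtDNA	L0d2a
HES043	mtDNA	L0d2a
HES044	mtDNA	L0d2a
HES045	mtDNA	L0d2a
HES046	mtDNA	L0d2a
HES047	mtDNA	L0d2a
HES048	mtDNA	L0d2a
HES049	mtDNA	L0d2a
HES050	mtDNA	L0d2a
HES051	mtDNA	L0d2a
HES052	mtDNA	L0d2a
HES053	mtDNA	L0d2a
HES054	mtDNA	L0d2a
HES055	mtDNA	L0d3
HES056	mtDNA	L0d3
HES057	mtDNA	L0d3
HES058	mtDNA	L0d3
HES059	mtDNA	L4b1
HES060	mtDNA	L5a1
HES061	mtDNA	L0a1
HES062	mtDNA	L0a1
HES063	mtDNA	L0a1
HES064	mtDNA	L1b1
HES065	mtDNA	L1b1
HES066	mtDNA	L2a1
HES067	mtDNA	L2a1
HES068	mtDNA	L2a1
HES069	mtDNA	L2a1
HES070	mtDNA	L3d1
HES071	mtDNA	L3d1
HES072	mtDNA	L3e2
HES073	mtDNA	L3e2
HES074	mtDNA	M2a
HES075	mtDNA	M2a
HES076	mtDNA	M2a
HES077	mtDNA	M2a
HES078	mtDNA	B4a
HES079	mtDNA	B4a
HES080	mtDNA	E1a
HES081	mtDNA	E1a
HES082	mtDNA	U7a
HES083	mtDNA	U7a
HES084	mtDNA	U7a
HES085	mtDNA	H
HES086	mtDNA	J1c
HES087	mtDNA	U2a1a
HESM001	Y	A1b1
HESM002	Y	A1b1
HESM003	Y	A1b1
HESM004	Y	A1b1
HESM005	Y	E1b1b
HESM006	Y	E1b1b
HESM007	Y	E1b1b
HESM008	Y	E1b1b
HESM009	Y	E1b1b
HESM010	Y	E1b1a
HESM011	Y	E1b1a
HESM012	Y	E1b1a
HESM013	Y	E1b1a
HESM014	Y	E1b1a
HESM015	Y	E1b1a
HESM016	Y	E1b1a
HESM017	Y	E1b1a
HESM018	Y	E1b1a
HESM019	Y	E1b1a
HESM020	Y	E1b1a
HESM021	Y	E1b1a
HESM022	Y	R1b
HESM023	Y	R1b
HESM024	Y	R1b
HESM025	Y	R1b
HESM026	Y	R1b
HESM027	Y	R1b
HESM028	Y	R1b
HESM029	Y	R1b
HESM030	Y	R1b
HESM031	Y	R1b
HESM032	Y	R1b
HESM033	Y	R1b
HESM034	Y	R1b
HESM035	Y	R1b
HESM036	Y	R1a
HESM037	Y	R1a
HESM038	Y	R1a
HESM039	Y	R1a
HESM040	Y	I1
HESM041	Y	I1
HESM042	Y	I1
HESM043	Y	I1
HESM044	Y	I1
HESM045	Y	I1
HESM046	Y	O1
HESM047	Y	O1
HESM048	Y	O1
HESM049	Y	O1
HESM050	Y	O2
HESM051	Y	O2
HESM052	Y	O2
HESM053	Y	C3
HESM054	Y	C3
HESM055	Y	L1a
HESM056	Y	L1a
HESM057	Y	H1a
HESM058	Y	H1a
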