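ligand	receptor	source
g001	g002	synthA
g003	g004	synthB
g005	g006	synthC
g007	g008	synthA
g009	g010	synthB
g011	g012	synthC
g013	g014	synthA
g015	g016	synthB
g017	g018	synthC
g019	g020	synthA
g021	g022	synthB
g023	g024	synthC
g025	g026	synthA
g027	g028	synthB
g029	g030	synthC
g031	g032	synthA
g033	g034	synthB
g035	g036	synthC
g037	g038	synthA
g039	g040	synthB
g041	g042	synthC
g043	g044	synthA
g045	g046	synthB
g047	g048	synthC
g049	g050	synthA
g051	g052	synthB
g053	g054	synthC
g055	g056	synthA
g057	g058	synthB
g059	g060	synthC
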