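sample_id	Otu001	Otu002	Otu003	Otu004	Otu005	Otu006	Otu007	Otu008	Otu009	Otu010	Otu011	Otu012	Otu013	Otu014	Otu015	Otu016	Otu017	Otu018	Otu019	Otu020	Otu021	Otu022	Otu023	Otu024	Otu025	Otu026	Otu027	Otu028	Otu029	Otu030	Otu031	Otu032	Otu033	Otu034	Otu035	Otu036	Otu037	Otu038	Otu039	Otu040	Otu041	Otu042	Otu043	Otu044	Otu045	Otu046	Otu047	Otu048	Otu049	Otu050	Otu051	Otu052	Otu053	Otu054	Otu055	Otu056	Otu057	Otu058	Otu059	Otu060	Otu061	Otu062	Otu063	Otu064	Otu065	Otu066	Otu067	Otu068	Otu069	Otu070	Otu071	Otu072	Otu073	Otu074	Otu075	Otu076	Otu077	Otu078	Otu079	Otu080	Otu081	Otu082	Otu083	Otu084	Otu085	Otu086	Otu087	Otu088	Otu089	Otu090	Otu091	Otu092	Otu093	Otu094	Otu095	Otu096	Otu097	Otu098	Otu099	Otu100	Otu101	Otu102	Otu103	Otu104	Otu105	Otu106	Otu107	Otu108	Otu109	Otu110	Otu111	Otu112	Otu113	Otu114	Otu115	Otu116	Otu117	Otu118	Otu119	Otu120	Otu121	Otu122	Otu123	Otu124	Otu125	Otu126	Otu127	Otu128	Otu129	Otu130	Otu131	Otu132
H01	33	30	28	27	27	25	21	19	17	16	16	15	14	13	13	12	12	12	11	11	11	10	9	8	8	8	7	7	7	6	6	5	5	4	4	4	4	4	4	4	3	3	3	3	3	3	3	3	3	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
H02	29	20	20	14	14	13	13	13	13	12	12	12	11	11	11	10	9	9	9	8	8	8	7	7	7	7	7	7	7	6	6	6	6	6	6	6	6	6	6	6	5	5	5	5	5	5	5	5	5	5	4	4	4	4	4	4	4	4	4	4	3	3	3	3	3	3	3	3	3	3	3	3	3	2	2	2	2	2	2	2	2	2	2	2	2	2	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
H03	9	7	7	6	6	6	5	5	5	5	5	5	5	5	5	4	4	4	4	4	4	4	4	4	3	3	3	3	3	3	3	3	3	3	3	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
C01	26	26	23	19	18	13	12	12	11	11	10	9	7	6	6	6	6	5	5	5	5	5	4	4	4	4	4	4	4	4	4	3	3	3	3	3	3	3	3	3	3	3	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
C02	23	21	18	14	12	11	10	10	10	9	8	8	8	8	8	7	7	7	7	7	6	6	6	6	6	6	6	6	5	5	5	5	5	5	5	5	4	4	4	4	4	4	3	3	3	3	3	3	3	3	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	0	0	0	0	0	0	0
C03	20	19	14	12	10	10	10	8	8	8	7	6	6	5	5	4	4	4	3	3	3	3	3	3	2	2	2	2	2	2	2	2	2	2	2	2	2	2	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
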