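abbreviation	carbon_count	double_bonds	hydroxyl_position	full_name
12:0	12	0		lauric acid
13:0	13	0		tridecylic acid
14:0	14	0		myristic acid
14:1	14	1		myristoleic acid
15:0	15	0		pentadecylic acid
16:0	16	0		palmitic acid
16:1	16	1		palmitoleic acid
17:0	17	0		margaric acid
18:0	18	0		stearic acid
18:1	18	1		oleic acid
18:2	18	2		linoleic acid
18:3	18	3		alpha-linolenic acid
19:0	19	0		nonadecylic acid
20:0	20	0		arachidic acid
20:1	20	1		gondoic acid
20:2	20	2		eicosadienoic acid
20:3	20	3		dihomo-gamma-linolenic acid
20:4	20	4		arachidonic acid
20:5	20	5		eicosapentaenoic acid
22:0	22	0		behenic acid
22:5	22	5		docosapentaenoic acid
22:6	22	6		docosahexaenoic acid
24:0	24	0		lignoceric acid
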