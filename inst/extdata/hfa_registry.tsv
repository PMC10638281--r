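abbreviation	carbon_count	double_bonds	hydroxyl_position	full_name
9-OH-12:0	12	0	9	9-hydroxy lauric acid (synthetic placeholder)
9-OH-13:0	13	0	9	9-hydroxy tridecylic acid (synthetic placeholder)
9-OH-14:0	14	0	9	9-hydroxy myristic acid (synthetic placeholder)
9-OH-14:1	14	1	9	9-hydroxy myristoleic acid (synthetic placeholder)
9-OH-15:0	15	0	9	9-hydroxy pentadecylic acid (synthetic placeholder)
9-OH-16:0	16	0	9	9-hydroxy palmitic acid (synthetic placeholder)
9-OH-16:1	16	1	9	9-hydroxy palmitoleic acid (synthetic placeholder)
9-OH-17:0	17	0	9	9-hydroxy margaric acid (synthetic placeholder)
9-OH-18:0	18	0	9	9-hydroxy stearic acid (synthetic placeholder)
9-OH-18:1	18	1	9	9-hydroxy oleic acid (synthetic placeholder)
9-OH-18:2	18	2	9	9-hydroxy linoleic acid (synthetic placeholder)
9-OH-18:3	18	3	9	9-hydroxy alpha-linolenic acid (synthetic placeholder)
9-OH-19:0	19	0	9	9-hydroxy nonadecylic acid (synthetic placeholder)
9-OH-20:0	20	0	9	9-hydroxy arachidic acid (synthetic placeholder)
9-OH-20:1	20	1	9	9-hydroxy gondoic acid (synthetic placeholder)
9-OH-20:2	20	2	9	9-hydroxy eicosadienoic acid (synthetic placeholder)
9-OH-20:3	20	3	9	9-hydroxy dihomo-gamma-linolenic acid (synthetic placeholder)
9-OH-20:4	20	4	9	9-hydroxy arachidonic acid (synthetic placeholder)
9-OH-20:5	20	5	9	9-hydroxy eicosapentaenoic acid (synthetic placeholder)
9-OH-22:0	22	0	9	9-hydroxy behenic acid (synthetic placeholder)
9-OH-22:5	22	5	9	9-hydroxy docosapentaenoic acid (synthetic placeholder)
9-OH-22:6	22	6	9	9-hydroxy docosahexaenoic acid (synthetic placeholder)
9-OH-24:0	24	0	9	9-hydroxy lignoceric acid (synthetic placeholder)
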