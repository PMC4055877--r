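scaffold_id	variant_id	name	smiles	set
1	1	methyl	*C	C
2	1	ethyl	*CC	C
3	1	n-propyl	*CCC	C
3	2	isopropyl	*C(C)C	C
4	1	n-butyl	*CCCC	C
4	2	sec-butyl	*C(C)CC	C
4	3	isobutyl	*CC(C)C	C
4	4	tert-butyl	*C(C)(C)C	C
4	5	n-pentyl	*CCCCC	B
4	6	neopentyl	*CC(C)(C)C	B
4	7	pentan-3-yl	*C(CC)CC	B
4	8	n-hexyl	*CCCCCC	A
4	9	isopentyl	*CCC(C)C	A
4	10	pentan-2-yl	*C(C)CCC	A
5	1	cyclopropyl	*C1CC1	C
5	2	cyclobutyl	*C1CCC1	C
5	3	cyclopentyl	*C1CCCC1	C
5	4	cyclohexyl	*C1CCCCC1	C
5	5	cyclohexylmethyl	*CC1CCCCC1	B
5	6	cyclopropylmethyl	*CC1CC1	A
5	7	cyclobutylmethyl	*CC1CCC1	A
5	8	cyclopentylmethyl	*CC1CCCC1	A
5	9	2-cyclopentylethyl	*CCC1CCCC1	A
5	10	4-methylcyclohexyl	*C1CCC(C)CC1	A
5	11	1-methylcyclohexyl	*C1(C)CCCCC1	A
5	12	cycloheptyl	*C1CCCCCC1	A
6	1	vinyl	*C=C	C
6	2	allyl	*CC=C	C
6	3	isopropenyl	*C(=C)C	C
6	4	prop-1-enyl	*C=CC	B
6	5	methallyl	*CC(=C)C	B
6	6	but-3-enyl	*CCC=C	A
6	7	but-1-enyl	*C=CCC	A
6	8	but-2-enyl	*CC=CC	A
6	9	buta-1,3-dienyl	*C=CC=C	A
6	10	3-methylbut-2-enyl	*CC=C(C)C	A
7	1	ethynyl	*C#C	B
7	2	propargyl	*CC#C	B
8	1	phenyl	*c1ccccc1	C
8	2	p-tolyl	*c1ccc(C)cc1	C
8	3	o-tolyl	*c1ccccc1C	A
8	4	m-tolyl	*c1cccc(C)c1	A
8	5	2,4-dimethylphenyl	*c1ccc(C)cc1C	A
8	6	4-ethylphenyl	*c1ccc(CC)cc1	A
9	1	naphthalen-1-yl	*c1cccc2ccccc12	C
9	2	naphthalen-2-yl	*c1ccc2ccccc2c1	C
9	3	biphenyl-4-yl	*c1ccc(-c2ccccc2)cc1	C
9	4	biphenyl-3-yl	*c1cccc(-c2ccccc2)c1	A
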