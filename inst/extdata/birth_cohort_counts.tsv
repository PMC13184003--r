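block	label	n_total	n_without	n_with
total	N	2665478	2641405	24073
sex	male	1363723	1360311	3412
sex	female	1301755	1281094	20661
birth_year	1973-1977	465343	462044	3299
birth_year	1978-1982	424509	420446	4063
birth_year	1983-1987	442644	437434	5210
birth_year	1988-1992	544529	538404	6125
birth_year	1993-1997	467750	463787	3963
birth_year	1998-2001	320703	319290	1413
phenotype	alcohol_use_disorder	116949	109169	7780
phenotype	drug_use_disorder	86275	77165	9110
phenotype	depressive_disorder	237283	218851	18432
phenotype	anxiety_disorder	109073	99742	9331
phenotype	ptsd	26522	21602	4920
phenotype	adhd	137632	128488	9144
phenotype	sleep_disorder	87005	82079	4926
phenotype	asthma	211592	208236	3356
phenotype	infections	1024938	1009137	15801
phenotype	cardiovascular_disease	116065	113957	2108
phenotype	self_harm	114112	102349	11763
phenotype	suicide	6933	6297	636
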