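patient_id	sample_id	sample_class	gene	variant_key	protein_change	gnomad_af	exac_af	dbsnp_id	cgc_role	cosmic_exact_match
P01	P01_biopsy	biopsy	ARID1A	chr1:27022894:G:A	p.R693Q	0.015	0.012			FALSE
P02	P02_biopsy	biopsy	GATA6	chr18:19751245:C:T	p.S184L			rs7236481		FALSE
P03	P03_biopsy	biopsy	KRAS	chr12:25398284:C:T	p.G12D	0.004		rs121913529	oncogene	TRUE
P21	P21_pdx	pdx	RNF43	chr17:56435161:T:C	p.I47V					FALSE
P22	P22_pdx	pdx	RNF43	chr17:56435161:T:C	p.I47V					FALSE
P04	P04_biopsy	biopsy	TP53	chr17:7577538:C:T	p.R248Q				tumor_suppressor	TRUE
P05	P05_biopsy	biopsy	SMAD4	chr18:48591918:C:T	p.R361C				tumor_suppressor	FALSE
P06	P06_biopsy	biopsy	CDKN2A	chr9:21971120:G:A	p.R80*				tumor_suppressor	FALSE
P07	P07_biopsy	biopsy	TGFBR2	chr3:30691871:A:G	p.T315A					FALSE
P08	P08_biopsy	biopsy	MSH6	chr2:48018081:C:T	p.R482W					FALSE
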