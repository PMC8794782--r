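qtl	gene	name	stop_gain_or_loss	missense_in_domain	sift_deleterious	sift_tolerated	promoter_or_splice	utr	enhancer	ctcf	de_any	kegg	expected_score
Gatlgq	ENSMUSG_PLG	Plg	FALSE	TRUE	FALSE	TRUE	TRUE	FALSE	TRUE	TRUE	FALSE	TRUE	10
Gatlgq	ENSMUSG_ACAT2	Acat2	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	TRUE	TRUE	9
Gatq1	ENSMUSG_FMO5	Fmo5	FALSE	TRUE	FALSE	TRUE	TRUE	TRUE	TRUE	FALSE	TRUE	TRUE	12
Gatq1	ENSMUSG_NOTCH2	Notch2	FALSE	TRUE	TRUE	FALSE	FALSE	TRUE	FALSE	FALSE	TRUE	TRUE	10
Bwq26	ENSMUSG_TRAP1	Trap1	FALSE	TRUE	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	TRUE	TRUE	7
Bwq26	ENSMUSG_RRN3	Rrn3	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	TRUE	TRUE	4
Gatq2	ENSMUSG_TRAPPC9	Trappc9	FALSE	FALSE	FALSE	FALSE	TRUE	TRUE	TRUE	TRUE	TRUE	TRUE	9
Gatq2	ENSMUSG_ZFAT	Zfat	FALSE	TRUE	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	TRUE	FALSE	8
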