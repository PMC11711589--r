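motif	modification_type	modified_index	label	distribution	in_rebase	avg_methylation_frequency
ACGGAG	6mA	5	ACGGAG	core	no	0.0872
CCCGGG	4mC	2	CCCGGG	core	yes	0.0595
CGATCG	6mA	3	CGATCG	shell	yes	0.0864
CTCGAG	6mA	5	CTCGAG	core	yes	0.1927
CTGCAG	6mA	5	CTGCAG	shell	yes	0.0849
CTYCCAG	6mA	6	CTYCCAG	core	no	0.0569
GANTC	6mA	2	GANTC	core	yes	0.9913
GCCAGG	6mA	4	GCCAGG	shell	yes	0.0162
GCCGGC	4mC	2	GCCGGC	core	yes	0.0605
GCRDB	4mC	2	GCRDB	core	no	0.0417
RAGCWGCTY	4mC	7	RAGCWGCTY	shell	no	0.0384
RCCAGCC	4mC	3	RCCAGCC	core	no	0.1831
RGATCY	6mA	3	RGATCY	shell	yes	0.0564
TCGWCGA	4mC	2	TCGWCGA	core	yes	0.1625
TGGGCA	6mA	6	TGGGCA	shell	no	0.0536
YCGGCCGRV	4mC	6	YCGGCCGRV	core	no	0.0948
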