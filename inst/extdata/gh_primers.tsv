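pair	role	name	seq	start	end	tm_c	usage
GH	forward	GH-forward	CTGAGCCGCAAACAGAGCC	-26	-8	60	cDNA cloning
GH	reverse	GH-reverse	AAAACTTCTGATGTCACGATTACCA	727	751	60	cDNA cloning
rt-GH	forward	rt-GH-forward	ATCAGGGCCAATCAGGATGA	409	428	60	qPCR target gene
rt-GH	reverse	rt-GH-reverse	GTGCATGTCCTTCTTGAAGCAA	537	558	60	qPCR target gene
rt-actin	forward	rt-actin-forward	CCACAGCCGAGAGGGAAAT	605	623	60	qPCR reference gene
rt-actin	reverse	rt-actin-reverse	CCATCTCCTGCTCGAAGTC	664	682	60	qPCR reference gene
pyr-GH	forward	pyr-GH-forward	GAAGCAGAGAATTATCCTGACAC	427	449	60	PCR before pyrosequencing
pyr-GH	reverse	pyr-GH-reverse	CAAGCCAGCAATTCATAAGTT	519	539	60	PCR before pyrosequencing
pyr-GH-seq	sequencing	pyr-GH	ACTATTATCAAAGTCTGGGAG	479	499	NA	pyrosequencing
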