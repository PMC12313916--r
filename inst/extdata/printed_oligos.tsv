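name	sequence	role	orientation_note
install_spacer	GAAGCAGCACGACUUCUUCA	CBE install guide (BE4max-SpCas9-NG), target C at spacer position 5	sense of WT CDS
sgRNA1	CGUGCUACUUCAUGUGGUCG	ABE8e reversion guide, target A at spacer position 7	antisense of mutant CDS
sgRNA2	GUCGUGCUACUUCAUGUGGU	ABE8e reversion guide, target A at spacer position 9	antisense of mutant CDS
sgRNA3	UCGUGCUACUUCAUGUGGUC	ABE8e reversion guide, target A at spacer position 8	antisense of mutant CDS
sa_spacer	AGUCGUGCUACUUCAUGUGGU	SaABE8e reversion guide (21-mer, NNGRRT PAM)	antisense of mutant CDS
ddpcr_fwd	ATCTTCTTCAAGGACGACGGCAAC	ddPCR forward primer, EGFP copy-number assay	sense of CDS
ddpcr_rev	AGCTCGATGCGGTTCACCAG	ddPCR reverse primer, EGFP copy-number assay	antisense of CDS
ddpcr_probe	TCGCCCTCGAACTTCACCTCGGCGC	ddPCR HEX probe (linker removed), EGFP copy-number assay	antisense of CDS
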