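protein_name	gene_names	fold_change	p_value
SH3 domain–binding glutamic acid–rich-like protein 3	Sh3bgrl3	2206.8	0.00024
Proliferation-associated protein 2G4	Pa2g4	275.7	0.0063
Smoothelin	Smtn	99.6	0.0011
Sorbin and SH3 domain–containing protein 2	Sorbs2	87.4	0.019
60S ribosomal protein L5	Rpl5	63.7	0.0012
Ribosome-binding protein 1	Rrbp1	57.2	0.047
PDZ and LIM domain protein 7	Pdlim7	51.1	0.0053
Mitogen-activated protein kinase 1	Mapk1	45.2	0.00098
PDZ and LIM domain protein 5	Pdlim5	37.7	0.00099
Testin	Tes	35.6	0.0041
Glycylpeptide N-tetradecanoyltransferase 1	Nmt1	35.5	0.053
Collagen alpha-2(I) chain	Col1a2	32.6	0.052
Nestin	Nes	30.9	0.0027
Procollagen C-endopeptidase enhancer 1	Pcolce	30.2	0.021
ATP-dependent Clp protease ATP-binding subunit clpX-like, mitochondrial	Clpx	27	0.0041
Peptidyl-prolyl cis–trans isomerase B	Ppib	27	0.023
2,4-dienoyl-CoA reductase, mitochondrial	Decr1	26.3	0.018
NADH-cytochrome b5 reductase 3; NADH-cytochrome b5 reductase 3 membrane-bound form; NADH-cytochrome b5 reductase 3 soluble form	Cyb5r3	23.9	0.0064
Structural maintenance of chromosomes protein 2	Smc2	22	0.008
Tubulin beta-3 chain	Tubb3	21.1	0.0023
Prolyl 4-hydroxylase subunit alpha-1	P4ha1	18.3	0.0034
Dedicator of cytokinesis protein 7	Dock7	17.1	0.05
Filamin A-interacting protein 1-like	Filip1l	16.3	0.014
Transcription factor BTF3	Btf3	15.5	0.033
Pleckstrin homology-like domain family B member 1	Phldb1	14.9	0.026
Epiplakin	Eppk1	14.3	0.038
Guanine nucleotide-binding protein G(s) subunit alpha isoforms short; guanine nucleotide-binding protein G(s) subunit alpha isoforms XLas	Gnas	13.9	0.0047
Leucine–tRNA ligase, cytoplasmic	Lars	13.7	0.051
Dolichyl-diphosphooligosaccharide--protein glycosyltransferase 48 kDa subunit	Ddost	13.6	0.041
Actin-binding protein anillin	Anln	12.6	0.017
Leucine zipper protein 1	Luzp1	12.1	0.032
Microtubule-associated protein 2	Map2	11.6	0.0011
Sulfide:quinone oxidoreductase, mitochondrial	Sqrdl	11.6	0.044
NADH dehydrogenase (ubiquinone) 1 alpha subcomplex subunit 8	Ndufa8	11.5	0.026
Myb-binding protein 1A	Mybbp1a	10.9	0.011
Fibulin-2	Fbln2	10.4	0.02
Annexin A6	Anxa6	10.4	0.03
Leiomodin-1	Lmod1	8.9	0.00064
Protein-lysine 6-oxidase	Lox	8.5	0.012
60S ribosomal protein L4	Rpl4	8.4	0.021
ATP-binding cassette subfamily F member 1	Abcf1	7.8	0.019
Collagen alpha-1(I) chain	Col1a1	7.7	0.023
Filamin-C	Flnc	7.5	0.0028
Ras GTPase-activating-like protein IQGAP1	Iqgap1	7.3	0.019
Tubulointerstitial nephritis antigen-like	Tinagl1	6.8	0.0055
Aspartyl/asparaginyl beta-hydroxylase	Asph	6.6	0.012
Collagen alpha-1(XII) chain	Col12a1	6	0.0037
Tubulin beta-2B chain	Tubb2b	5.8	0.046
Nascent polypeptide-associated complex subunit alpha, muscle-specific form; nascent polypeptide-associated complex subunit alpha	Naca	5.1	0.001
Paired mesoderm homeobox protein 2; paired mesoderm homeobox protein 1	Prrx2; Prrx1	4.9	0.0011
60S ribosomal protein L34	Rpl34	4.5	0.025
Reticulon-4	Rtn4	4.2	0.052
Vigilin	Hdlbp	4.2	0.04
Fibronectin; anastellin	Fn1	4.2	0.00049
Ras-related protein Rab-2A; Ras-related protein Rab-2B	Rab2a; Rab2b	4.1	0.038
Protein-glutamine gamma-glutamyltransferase 2	Tgm2	3.9	0.012
40S ribosomal protein S16	Rps16	3.8	0.014
40S ribosomal protein S28	Rps28	3.7	0.03
Thrombospondin-1	Thbs1	3.7	0.029
Tubulin alpha-1A chain; tubulin alpha-3 chain	Tuba1a; Tuba3a	3.6	0.0053
40S ribosomal protein S23	Rps23	3.5	0.0036
Serine/threonine-protein phosphatase 2A 55 kDa regulatory subunit B alpha isoform; serine/threonine-protein phosphatase 2A 55 kDa regulatory subunit B delta isoform	Ppp2r2a; Ppp2r2d	3.5	0.017
ADP-ribosylation factor-like protein 8A; ADP-ribosylation factor-like protein 8B	Arl8a; Arl8b	3.4	0.035
A-kinase anchor protein 2	Akap2	3.2	0.021
Bystin	Bysl	3.2	0.045
40S ribosomal protein S2	Rps2	3.1	0.0027
Developmentally regulated GTP-binding protein 1	Drg1	3.1	0.013
60S ribosomal protein L18a	Rpl18a	2.9	0.044
60S ribosomal protein L13	Rpl13	2.9	0.01
60S ribosomal protein L26	Rpl26	2.9	0.024
Calponin-2	Cnn2	2.8	0.016
GMP synthase (glutamine-hydrolyzing)	Gmps	2.8	0.013
Serine/arginine-rich splicing factor 2	Srsf2	2.7	0.051
RNA-binding protein 3	Rbm3	2.6	0.00024
40S ribosomal protein S5; 40S ribosomal protein S5, N-terminally processed	Rps5	2.5	0.023
LIM and SH3 domain protein 1	Lasp1	2.5	0.012
Allograft inflammatory factor 1-like	Aif1l	2.5	0.008
60S ribosomal protein L38	Rpl38	2.5	0.052
Succinyl-CoA ligase (ADP/GDP-forming) subunit alpha, mitochondrial	Suclg1	2.4	0.03
Serine/arginine-rich splicing factor 3	Srsf3	2.4	0.0027
60S ribosomal protein L27	Rpl27	2.4	0.016
Alpha-crystallin B chain	Cryab	2.3	0.025
Serine/threonine-protein kinase DCLK1	Dclk1	2.3	0.0024
Ubiquitin-associated protein 2-like	Ubap2l	2.2	0.011
40S ribosomal protein S3a	Rps3a	2.2	0.0035
40S ribosomal protein S14	Rps14	2.2	0.026
Aminoacyl tRNA synthase complex-interacting multifunctional protein 2	Aimp2	2.2	0.018
60S ribosomal protein L27a	Rpl27a	2.2	0.052
F-actin-capping protein subunit alpha-1	Capza1	2.1	0.03
Heterogeneous nuclear ribonucleoprotein F; heterogeneous nuclear ribonucleoprotein F, N-terminally processed	Hnrnpf	2.1	0.016
Uridine 5-monophosphate synthase; orotate phosphoribosyltransferase; orotidine 5-phosphate decarboxylase	Umps	2	0.047
ATP-dependent RNA helicase DDX3X; putative ATP-dependent RNA helicase Pl10	Ddx3x; D1Pas1	2	0.052
Protein hook homolog 3	Hook3	2	0.038
ATP synthase subunit O, mitochondrial	Atp5o	1.9	0.025
Heterogeneous nuclear ribonucleoprotein U	Hnrnpu	1.9	0.042
Eukaryotic initiation factor 4A-I	Eif4a1	1.9	0.052
Filamin-B	Flnb	1.8	0.024
Heterogeneous nuclear ribonucleoprotein H; heterogeneous nuclear ribonucleoprotein H, N-terminally processed	Hnrnph1	1.7	0.035
Ataxin-2-like protein	Atxn2l	1.7	0.0039
Polypyrimidine tract-binding protein 1	Ptbp1	1.7	0.025
40S ribosomal protein S27; 40S ribosomal protein S27-like	Rps27; Rps27l	1.7	0.043
Protein S100-A4	S100a4	1.7	0.031
ELAV-like protein 1	Elavl1	1.6	0.023
Actin, alpha cardiac muscle 1; actin, alpha skeletal muscle	Actc1; Acta1	1.6	0.044
Poly(rC)-binding protein 2	Pcbp2	1.6	0.042
CTP synthase 1	Ctps1	1.6	0.0098
60S ribosomal protein L9	Rpl9	1.5	0.008
Nuclease-sensitive element-binding protein 1	Ybx1	1.5	0.05
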