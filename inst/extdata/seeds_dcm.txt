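# Dilated cardiomyopathy (DCM) seed genes, OMIM-derived
# columns: official gene symbol <TAB> protein accession
NEXN	Q0ZGT2
LMNA	P02545
TNNT2	P45379
PSEN2	P49810
ACTN2	P35609
TTN	Q8WZ42
DES	P17661
SCN5A	Q14524
TNNC1	P63316
SDHA	P31040
SGCD	Q92629
DSP	P15924
PLN	P26678
EYA4	O95677
GATAD1	Q8WUU5
FKTN	O75072
VCL	P18206
LDB3	O75112
RBM20	Q5T481
BAG3	O95817
CSRP3	P50461
MYBPC3	Q14896
ABCC9	O60706
TMPO	P42166
MYH6	P13533
MYH7	P12883
PSEN1	P49768
ACTC1	P68032
TPM1	P09493
TCAP	O15273
DSG2	Q14126
TNNI3	P19429
DMD	P11532
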