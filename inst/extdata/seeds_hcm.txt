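# Hypertrophic cardiomyopathy (HCM) seed genes, OMIM-derived
# columns: official gene symbol <TAB> protein accession
NEXN	Q0ZGT2
TNNT2	P45379
TTN	Q8WZ42
CAV3	P56539
MYL3	P08590
TNNC1	P63316
MYOZ2	Q9NPC6
SLC25A4	P12235
MYO6	Q9UM54
PLN	P26678
PRKAG2	Q9UGJ0
VCL	P18206
COX15	Q7KZN9
CSRP3	P50461
MYBPC3	Q14896
MYL2	P10916
MYH6	P13533
MYH7	P12883
ACTC1	P68032
TPM1	P09493
CALR3	Q96L12
TNNI3	P19429
MYLK2	Q9H1R3
JPH2	Q9BR39
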