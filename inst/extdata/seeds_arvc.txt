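# Arrhythmogenic right ventricular cardiomyopathy (ARVC) seed genes, OMIM-derived
# columns: official gene symbol <TAB> protein accession
RYR2	Q92736
TMEM43	Q9BTV4
RPSA	P08865
DSP	P15924
PKP2	Q99959
TGFB3	P10600
JUP	P14923
DSC2	Q02487
DSG2	Q14126
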