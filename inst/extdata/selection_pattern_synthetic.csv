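variable,index,coefficient
ICAM-1 BAS,IT_mean,0.30
ICAM-1 BAS,IT_median,0.25
IL6 BAS,IT_mean,0.20
IL6 BAS,IT_median,0.22
TNFa,IT_mean,0.35
TNFa,IT_median,0.30
TNFa,LA_mean,0.40
oxLDL,IT_mean,0.45
oxLDL,LA_median,0.38
HDL,IT_median,0.33
HDL,LA_median,0.28
ICAM-1 END-DIET,LA_mean,0.15
ICAM-1 END-DIET,LA_median,0.18
CATA,IT_mean,0.50
CATA,IT_median,0.46
CATA,LA_mean,0.44
CATA,LA_median,0.41
CATD,IT_mean,0.48
CATD,LA_mean,0.40
CATD,LA_median,0.36
BGH3,IT_mean,0.37
BGH3,LA_mean,0.33
BGH3,LA_median,0.30
S10AA,IT_mean,0.42
S10AA,IT_median,0.35
S10AA,LA_mean,0.31
FABPH,IT_mean,-0.45
FABPH,LA_mean,-0.39
G3P,IT_mean,0.30
G3P,IT_median,-0.28
G3P,LA_median,0.27
CPNS1,IT_mean,0.0005
CPNS1,IT_median,0.0007
CPNS1,LA_mean,0.0004
ANXA4,IT_mean,0.25
ANXA4,LA_mean,-0.24
ANXA4,LA_median,-0.22
PPCE,IT_median,0.21
PPCE,LA_mean,-0.20
PPCE,LA_median,0.19
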