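joint,group,zone,compartment,parameter,mean,sd
OA,SHAM,NA,LFC,Tb.A,42.57,5.15
OA,CONT,NA,LFC,Tb.A,49.57,11.26
OA,RIS,NA,LFC,Tb.A,41.82,8.46
HT,SHAM,NA,LFC,Tb.A,46.76,6.9
HT,CONT,NA,LFC,Tb.A,45.62,5.77
HT,RIS,NA,LFC,Tb.A,47.54,5.84
OA,SHAM,NA,MFC,Tb.A,45.32,3.77
OA,CONT,NA,MFC,Tb.A,44.58,6.23
OA,RIS,NA,MFC,Tb.A,46.11,11.04
HT,SHAM,NA,MFC,Tb.A,50.95,9.79
HT,CONT,NA,MFC,Tb.A,50.2,9.18
HT,RIS,NA,MFC,Tb.A,50.74,3.84
OA,SHAM,NA,LTP,Tb.A,62.05,3.7
OA,CONT,NA,LTP,Tb.A,48.99,6.19
OA,RIS,NA,LTP,Tb.A,54.74,8.96
HT,SHAM,NA,LTP,Tb.A,62.69,5.36
HT,CONT,NA,LTP,Tb.A,61.62,2.45
HT,RIS,NA,LTP,Tb.A,58.24,4.93
OA,SHAM,NA,MTP,Tb.A,49.44,9.54
OA,CONT,NA,MTP,Tb.A,41.52,8.56
OA,RIS,NA,MTP,Tb.A,45.7,11.85
HT,SHAM,NA,MTP,Tb.A,51.4,10.22
HT,CONT,NA,MTP,Tb.A,56.41,7.63
HT,RIS,NA,MTP,Tb.A,50.08,9.47
OA,SHAM,NA,LFC,Tb.Th,0.429,0.126
OA,CONT,NA,LFC,Tb.Th,0.399,0.177
OA,RIS,NA,LFC,Tb.Th,0.447,0.208
HT,SHAM,NA,LFC,Tb.Th,0.3,0.121
HT,CONT,NA,LFC,Tb.Th,0.34,0.14
HT,RIS,NA,LFC,Tb.Th,0.284,0.071
OA,SHAM,NA,MFC,Tb.Th,0.431,0.18
OA,CONT,NA,MFC,Tb.Th,0.448,0.208
OA,RIS,NA,MFC,Tb.Th,0.304,0.057
HT,SHAM,NA,MFC,Tb.Th,0.479,0.263
HT,CONT,NA,MFC,Tb.Th,0.47,0.218
HT,RIS,NA,MFC,Tb.Th,0.465,0.196
OA,SHAM,NA,LTP,Tb.Th,0.303,0.075
OA,CONT,NA,LTP,Tb.Th,0.26,0.9
OA,RIS,NA,LTP,Tb.Th,0.315,0.111
HT,SHAM,NA,LTP,Tb.Th,0.371,0.151
HT,CONT,NA,LTP,Tb.Th,0.337,0.063
HT,RIS,NA,LTP,Tb.Th,0.331,0.126
OA,SHAM,NA,MTP,Tb.Th,0.354,0.068
OA,CONT,NA,MTP,Tb.Th,0.407,0.17
OA,RIS,NA,MTP,Tb.Th,0.277,0.123
HT,SHAM,NA,MTP,Tb.Th,0.325,0.069
HT,CONT,NA,MTP,Tb.Th,0.336,0.114
HT,RIS,NA,MTP,Tb.Th,0.364,0.099
OA,SHAM,NA,LFC,Tb.Sp,0.425,0.074
OA,CONT,NA,LFC,Tb.Sp,0.476,0.192
OA,RIS,NA,LFC,Tb.Sp,0.42,0.18
HT,SHAM,NA,LFC,Tb.Sp,0.426,0.202
HT,CONT,NA,LFC,Tb.Sp,0.36,0.128
HT,RIS,NA,LFC,Tb.Sp,0.535,0.109
OA,SHAM,NA,MFC,Tb.Sp,0.423,0.149
OA,CONT,NA,MFC,Tb.Sp,0.438,0.199
OA,RIS,NA,MFC,Tb.Sp,0.344,0.085
HT,SHAM,NA,MFC,Tb.Sp,0.415,0.141
HT,CONT,NA,MFC,Tb.Sp,0.439,0.117
HT,RIS,NA,MFC,Tb.Sp,0.389,0.155
OA,SHAM,NA,LTP,Tb.Sp,0.222,0.116
OA,CONT,NA,LTP,Tb.Sp,0.301,0.093
OA,RIS,NA,LTP,Tb.Sp,0.242,0.113
HT,SHAM,NA,LTP,Tb.Sp,0.179,0.077
HT,CONT,NA,LTP,Tb.Sp,0.223,0.069
HT,RIS,NA,LTP,Tb.Sp,0.237,0.073
OA,SHAM,NA,MTP,Tb.Sp,0.403,0.245
OA,CONT,NA,MTP,Tb.Sp,0.404,0.182
OA,RIS,NA,MTP,Tb.Sp,0.432,0.244
HT,SHAM,NA,MTP,Tb.Sp,0.441,0.162
HT,CONT,NA,MTP,Tb.Sp,0.24,0.083
HT,RIS,NA,MTP,Tb.Sp,0.352,0.171
OA,SHAM,NA,LFC,Tb.N,3,0.632
OA,CONT,NA,LFC,Tb.N,3.125,0.641
OA,RIS,NA,LFC,Tb.N,3.286,0.756
HT,SHAM,NA,LFC,Tb.N,3.429,1.272
HT,CONT,NA,LFC,Tb.N,4.167,0.983
HT,RIS,NA,LFC,Tb.N,3.625,0.518
OA,SHAM,NA,MFC,Tb.N,3.286,0.951
OA,CONT,NA,MFC,Tb.N,3.75,1.282
OA,RIS,NA,MFC,Tb.N,3.167,1.329
HT,SHAM,NA,MFC,Tb.N,3.286,0.951
HT,CONT,NA,MFC,Tb.N,3.375,0.744
HT,RIS,NA,MFC,Tb.N,3.25,1.035
OA,SHAM,NA,LTP,Tb.N,4.143,0.69
OA,CONT,NA,LTP,Tb.N,3.875,0.641
OA,RIS,NA,LTP,Tb.N,4,0.926
HT,SHAM,NA,LTP,Tb.N,3.833,0.983
HT,CONT,NA,LTP,Tb.N,3.875,0.641
HT,RIS,NA,LTP,Tb.N,3.571,0.535
OA,SHAM,NA,MTP,Tb.N,3,0.816
OA,CONT,NA,MTP,Tb.N,2.375,0.518
OA,RIS,NA,MTP,Tb.N,2.75,1.035
HT,SHAM,NA,MTP,Tb.N,2.833,0.408
HT,CONT,NA,MTP,Tb.N,3.857,0.9
HT,RIS,NA,MTP,Tb.N,3.25,1.035
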