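joint,group,zone,compartment,parameter,mean,sd
OA,SHAM,Z1,LFC,FI,1.04,0.018
OA,SHAM,Z2,LFC,FI,1.03,0.024
OA,SHAM,Z3,LFC,FI,1.047,0.053
OA,SHAM,Z4,LFC,FI,1.086,0.055
HT,SHAM,Z1,LFC,FI,1.02,0.01
HT,SHAM,Z2,LFC,FI,1.01,0.01
HT,SHAM,Z3,LFC,FI,1.03,0.01
HT,SHAM,Z4,LFC,FI,1.051,0.024
OA,SHAM,Z1,MFC,FI,1.052,0.028
OA,SHAM,Z2,MFC,FI,1.024,0.031
OA,SHAM,Z3,MFC,FI,1.104,0.102
OA,SHAM,Z4,MFC,FI,1.11,0.063
HT,SHAM,Z1,MFC,FI,1.043,0.031
HT,SHAM,Z2,MFC,FI,1.034,0.025
HT,SHAM,Z3,MFC,FI,1.069,0.037
HT,SHAM,Z4,MFC,FI,1.081,0.041
OA,SHAM,Z1,LTP,FI,1.045,0.093
OA,SHAM,Z2,LTP,FI,1.011,0.019
OA,SHAM,Z3,LTP,FI,1.011,0.007
OA,SHAM,Z4,LTP,FI,1.021,0.041
HT,SHAM,Z1,LTP,FI,1.011,0.015
HT,SHAM,Z2,LTP,FI,1.01,0.016
HT,SHAM,Z3,LTP,FI,1.01,0.009
HT,SHAM,Z4,LTP,FI,1.04,0.051
OA,SHAM,Z1,MTP,FI,1.068,0.064
OA,SHAM,Z2,MTP,FI,1.194,0.233
OA,SHAM,Z3,MTP,FI,1.086,0.112
OA,SHAM,Z4,MTP,FI,1.066,0.07
HT,SHAM,Z1,MTP,FI,1.084,0.054
HT,SHAM,Z2,MTP,FI,1.1,0.04
HT,SHAM,Z3,MTP,FI,1.094,0.045
HT,SHAM,Z4,MTP,FI,1.09,0.06
OA,CONT,Z1,LFC,FI,1.04,0.019
OA,CONT,Z2,LFC,FI,1.042,0.054
OA,CONT,Z3,LFC,FI,1.059,0.08
OA,CONT,Z4,LFC,FI,1.08,0.033
HT,CONT,Z1,LFC,FI,1.032,0.027
HT,CONT,Z2,LFC,FI,1.019,0.012
HT,CONT,Z3,LFC,FI,1.031,0.02
HT,CONT,Z4,LFC,FI,1.044,0.024
OA,CONT,Z1,MFC,FI,1.088,0.05
OA,CONT,Z2,MFC,FI,1.153,0.185
OA,CONT,Z3,MFC,FI,1.15,0.17
OA,CONT,Z4,MFC,FI,1.141,0.051
HT,CONT,Z1,MFC,FI,1.033,0.025
HT,CONT,Z2,MFC,FI,1.015,0.011
HT,CONT,Z3,MFC,FI,1.03,0.015
HT,CONT,Z4,MFC,FI,1.044,0.008
OA,CONT,Z1,LTP,FI,1.111,0.095
OA,CONT,Z2,LTP,FI,1.152,0.241
OA,CONT,Z3,LTP,FI,1.073,0.095
OA,CONT,Z4,LTP,FI,1.092,0.094
HT,CONT,Z1,LTP,FI,1.025,0.039
HT,CONT,Z2,LTP,FI,1.02,0.019
HT,CONT,Z3,LTP,FI,1.024,0.021
HT,CONT,Z4,LTP,FI,1.006,0.006
OA,CONT,Z1,MTP,FI,1.179,0.147
OA,CONT,Z2,MTP,FI,1.313,0.251
OA,CONT,Z3,MTP,FI,1.234,0.114
OA,CONT,Z4,MTP,FI,1.262,0.146
HT,CONT,Z1,MTP,FI,1.088,0.05
HT,CONT,Z2,MTP,FI,1.105,0.064
HT,CONT,Z3,MTP,FI,1.07,0.074
HT,CONT,Z4,MTP,FI,1.067,0.048
OA,RIS,Z1,LFC,FI,1.201,0.17
OA,RIS,Z2,LFC,FI,1.133,0.105
OA,RIS,Z3,LFC,FI,1.158,0.12
OA,RIS,Z4,LFC,FI,1.126,0.045
HT,RIS,Z1,LFC,FI,1.03,0.022
HT,RIS,Z2,LFC,FI,1.038,0.036
HT,RIS,Z3,LFC,FI,1.025,0.009
HT,RIS,Z4,LFC,FI,1.058,0.04
OA,RIS,Z1,MFC,FI,1.17,0.179
OA,RIS,Z2,MFC,FI,1.156,0.077
OA,RIS,Z3,MFC,FI,1.193,0.176
OA,RIS,Z4,MFC,FI,1.195,0.136
HT,RIS,Z1,MFC,FI,1.016,0.012
HT,RIS,Z2,MFC,FI,1.029,0.031
HT,RIS,Z3,MFC,FI,1.073,0.062
HT,RIS,Z4,MFC,FI,1.075,0.048
OA,RIS,Z1,LTP,FI,1.147,0.166
OA,RIS,Z2,LTP,FI,1.094,0.149
OA,RIS,Z3,LTP,FI,1.083,0.067
OA,RIS,Z4,LTP,FI,1.088,0.141
HT,RIS,Z1,LTP,FI,1.023,0.04
HT,RIS,Z2,LTP,FI,1.013,0.025
HT,RIS,Z3,LTP,FI,1.026,0.033
HT,RIS,Z4,LTP,FI,1.01,0.022
OA,RIS,Z1,MTP,FI,1.136,0.157
OA,RIS,Z2,MTP,FI,1.292,0.252
OA,RIS,Z3,MTP,FI,1.241,0.278
OA,RIS,Z4,MTP,FI,1.156,0.099
HT,RIS,Z1,MTP,FI,1.066,0.066
HT,RIS,Z2,MTP,FI,1.095,0.074
HT,RIS,Z3,MTP,FI,1.085,0.048
HT,RIS,Z4,MTP,FI,1.033,0.043
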