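condition,variant,pip3_level,k1,k1_corrected,k2,k2_corrected,k3,k3_corrected,qk1,qk2,qk3,residual,lifetime_s,D1,D2,D3,qD1,qD2,qD3,molecules,cells
DdWT_lowPIP3,DdPTEN,low,0.11,NA,1.04,0.92,4.82,4.69,0.04,0.28,0.68,0.0060,4.62,0.01,0.05,0.52,0.67,0.30,0.03,1322,20
DdWT_highPIP3,DdPTEN,high,0.22,0.10,1.37,1.25,5.01,4.88,0.03,0.22,0.75,0.0078,1.72,0.01,0.05,0.43,0.41,0.56,0.03,1280,13
DdGE_lowPIP3,DdPTEN_G129E,low,0.13,0.01,1.05,0.93,5.06,4.93,0.04,0.25,0.71,0.0036,3.49,0.01,0.06,0.75,0.60,0.35,0.05,1318,19
DdGE_highPIP3,DdPTEN_G129E,high,0.18,0.05,1.36,1.23,4.14,4.01,0.04,0.27,0.69,0.0070,2.29,0.03,0.08,0.66,0.44,0.50,0.06,1490,19
HsWT_lowPIP3,HsPTEN,low,0.13,0.00,0.63,0.51,4.79,4.66,0.05,0.17,0.79,0.0066,4.25,0.02,0.07,0.53,0.66,0.26,0.08,781,24
HsWT_highPIP3,HsPTEN,high,0.32,0.20,1.85,1.73,6.30,6.17,0.05,0.25,0.70,0.0054,1.43,0.02,0.14,0.77,0.40,0.41,0.19,972,16
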