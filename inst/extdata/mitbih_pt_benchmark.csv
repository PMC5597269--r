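record,beats,p_tp,p_fp,p_fn,p_se,p_ppv,t_tp,t_fp,t_fn,t_se,t_ppv
100,2274,2274,0,0,100.00,100.00,2274,0,0,100.00,100.00
101,1866,1866,0,0,100.00,100.00,1863,3,0,100.00,99.84
102,2187,2021,87,79,96.37,96.02,2187,0,0,100.00,100.00
103,2084,2076,4,4,99.81,99.81,2084,0,0,100.00,100.00
104,2229,2071,82,76,96.58,96.32,2228,1,0,100.00,99.96
105,2602,2557,33,12,99.53,98.72,2579,15,8,99.69,99.42
106,2026,2013,12,1,99.95,99.41,2013,13,0,100.00,99.36
107,2136,2136,0,0,100.00,100.00,2136,0,0,100.00,100.00
108,1765,1363,244,158,90.56,86.13,1710,36,19,98.91,97.95
109,2533,2342,135,56,97.72,94.67,2532,1,0,100.00,99.96
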