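"","ATR","CST","CING","CINGh","FMaj","FMin","IFOF","ILF","SLF","UNC","Age"
"ATR",0,0.22,0.16,0,0,0.28,0,0,0.08,0.15,0.12
"CST",0.22,0,0.09,0,0.06,0,0,0,0.18,0,0.08
"CING",0.16,0.09,0,0.26,0,0,0,0,0.06,0,0.08
"CINGh",0,0,0.26,0,0.04,0,0,0.12,0,0.1,0.06
"FMaj",0,0.06,0,0.04,0,0.12,0,0.2,0,0,0.06
"FMin",0.28,0,0,0,0.12,0,0.14,0,0,0.08,0.12
"IFOF",0,0,0,0,0,0.14,0,0.44,0.11,0.25,0.1
"ILF",0,0,0,0.12,0.2,0,0.44,0,0.3,0.05,0.1
"SLF",0.08,0.18,0.06,0,0,0,0.11,0.3,0,0,0.08
"UNC",0.15,0,0,0.1,0,0.08,0.25,0.05,0,0,0.08
"Age",0.12,0.08,0.08,0.06,0.06,0.12,0.1,0.1,0.08,0.08,0
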