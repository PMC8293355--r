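"","NO","Read","Spell","Pea","MR","DR","BDR","Dot","MrX","FI","CAC","CMF","FP","MOF","RAC","RMF","SFG","STG","SMG","TTG","ATR","CST","CING","CINGh","FMaj","FMin","IFOF","ILF","SLF","UNC","Age"
"NO",0,0.15,0.08,0.11,0.13,0,0.04,0.08,0.03,0.07,0,0,0,0,0,0.06,0.04,0,0,0,0,0,0,0,0,0.06,0,0,0,0,0.06
"Read",0.15,0,0.63,0.16,0.07,0.06,0.04,0,0,0.03,0,0,0,0,0,0,0,0.06,0,0,0,0,0,0,0,0,0,0.05,0,0,0.06
"Spell",0.08,0.63,0,0.12,0.03,0.02,0.05,0,0,0,0,0,0,0,0,0,0,0,0.04,0,0,0,0,0,0,0,0.04,0,0,0,0.032
"Pea",0.11,0.16,0.12,0,0.09,0.05,0,0.02,0.02,0.07,0,0,0,0,0,0,0,0.06,0,0,0,0,0,0,0,0,0,0,0,0.06,0.04
"MR",0.13,0.07,0.03,0.09,0,0.04,0.06,0.1,0.08,0,0,0,0,0,0,0.06,0.05,0,0,0,0,0,0,0,0,0.05,0,0,0,0,0.048
"DR",0,0.06,0.02,0.05,0.04,0,0.27,0.1,0.07,0.1,0,0,0,0,0,0,0,0.04,0,0,0,0,0,0,0,0,0,0,0.04,0,0.032
"BDR",0.04,0.04,0.05,0,0.06,0.27,0,0.12,0.09,0.08,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.024
"Dot",0.08,0,0,0.02,0.1,0.1,0.12,0,0.21,0.07,0,0,0,0,0,0,0.05,0,0,0,0,0,0,0.04,0,0,0,0,0,0,0.032
"MrX",0.03,0,0,0.02,0.08,0.07,0.09,0.21,0,0.07,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.024
"FI",0.07,0.03,0,0.07,0,0.1,0.08,0.07,0.07,0,0,-0.05,0,0,0,0,0,0,0,0,0,0,0,0,0,-0.04,0,0,0,0,0.02
"CAC",0,0,0,0,0,0,0,0,0,0,0,0.08,0,0,0.38,0,0.14,0,0.05,0.08,0,0,0.06,0,0,0,0,0,0,0,0.024
"CMF",0,0,0,0,0,0,0,0,0,-0.05,0.08,0,-0.15,0.14,0,0.36,0.26,0,0,0,0,0,0,0,0,0,0,0,0,0,0.032
"FP",0,0,0,0,0,0,0,0,0,0,0,-0.15,0,0.12,0,0.1,0,0,0,0,0,0,0,0,0,-0.04,0,0,0,0,0.04
"MOF",0,0,0,0,0,0,0,0,0,0,0,0.14,0.12,0,0.3,0,0.04,0.1,0,0,0,0,0,0,0,0,0,0,0,0.05,0.024
"RAC",0,0,0,0,0,0,0,0,0,0,0.38,0,0,0.3,0,0.17,0.09,0,0,0,0,0,0,0,0,0,0,0,0,0,0.024
"RMF",0.06,0,0,0,0.06,0,0,0,0,0,0,0.36,0.1,0,0.17,0,0.34,0,0.12,0,0,0,0,0,0,0.06,0,0,0,0,0.032
"SFG",0.04,0,0,0,0.05,0,0,0.05,0,0,0.14,0.26,0,0.04,0.09,0.34,0,0.16,0,0,0.06,0,0,0,0,0,0,0,0,0,0.04
"STG",0,0.06,0,0.06,0,0.04,0,0,0,0,0,0,0,0.1,0,0,0.16,0,0.32,0.52,0,0,0,0,0,0,0,0.06,0,0,0.032
"SMG",0,0,0.04,0,0,0,0,0,0,0,0.05,0,0,0,0,0.12,0,0.32,0,0.2,0,0,0,0,0,0,0,0,0.05,0,0.024
"TTG",0,0,0,0,0,0,0,0,0,0,0.08,0,0,0,0,0,0,0.52,0.2,0,0,0,0,0,0,0,0.04,0,0,0,0.02
"ATR",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.06,0,0,0,0,0.22,0.16,0,0,0.28,0,0,0.08,0.15,0.048
"CST",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.22,0,0.09,0,0.06,0,0,0,0.18,0,0.032
"CING",0,0,0,0,0,0,0,0,0,0,0.06,0,0,0,0,0,0,0,0,0,0.16,0.09,0,0.26,0,0,0,0,0.06,0,0.032
"CINGh",0,0,0,0,0,0,0,0.04,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.26,0,0.04,0,0,0.12,0,0.1,0.024
"FMaj",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.06,0,0.04,0,0.12,0,0.2,0,0,0.024
"FMin",0.06,0,0,0,0.05,0,0,0,0,-0.04,0,0,-0.04,0,0,0.06,0,0,0,0,0.28,0,0,0,0.12,0,0.14,0,0,0.08,0.048
"IFOF",0,0,0.04,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.04,0,0,0,0,0,0.14,0,0.44,0.11,0.25,0.04
"ILF",0,0.05,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0.06,0,0,0,0,0,0.12,0.2,0,0.44,0,0.3,0.05,0.04
"SLF",0,0,0,0,0,0.04,0,0,0,0,0,0,0,0,0,0,0,0,0.05,0,0.08,0.18,0.06,0,0,0,0.11,0.3,0,0,0.032
"UNC",0,0,0,0.06,0,0,0,0,0,0,0,0,0,0.05,0,0,0,0,0,0,0.15,0,0,0.1,0,0.08,0.25,0.05,0,0,0.032
"Age",0.06,0.06,0.032,0.04,0.048,0.032,0.024,0.032,0.024,0.02,0.024,0.032,0.04,0.024,0.024,0.032,0.04,0.032,0.024,0.02,0.048,0.032,0.032,0.024,0.024,0.048,0.04,0.04,0.032,0.032,0
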