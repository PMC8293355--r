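"","NO","Read","Spell","Pea","MR","DR","BDR","Dot","MrX","FI","Age"
"NO",0,0.15,0.08,0.11,0.13,0,0.04,0.08,0.03,0.07,0.15
"Read",0.15,0,0.63,0.16,0.07,0.06,0.04,0,0,0.03,0.15
"Spell",0.08,0.63,0,0.12,0.03,0.02,0.05,0,0,0,0.08
"Pea",0.11,0.16,0.12,0,0.09,0.05,0,0.02,0.02,0.07,0.1
"MR",0.13,0.07,0.03,0.09,0,0.04,0.06,0.1,0.08,0,0.12
"DR",0,0.06,0.02,0.05,0.04,0,0.27,0.1,0.07,0.1,0.08
"BDR",0.04,0.04,0.05,0,0.06,0.27,0,0.12,0.09,0.08,0.06
"Dot",0.08,0,0,0.02,0.1,0.1,0.12,0,0.21,0.07,0.08
"MrX",0.03,0,0,0.02,0.08,0.07,0.09,0.21,0,0.07,0.06
"FI",0.07,0.03,0,0.07,0,0.1,0.08,0.07,0.07,0,0.05
"Age",0.15,0.15,0.08,0.1,0.12,0.08,0.06,0.08,0.06,0.05,0
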