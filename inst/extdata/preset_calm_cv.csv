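"","CAC","CMF","FP","MOF","RAC","RMF","SFG","STG","SMG","TTG","Age"
"CAC",0,0.08,0,0,0.38,0,0.14,0,0.05,0.08,0.06
"CMF",0.08,0,-0.15,0.14,0,0.36,0.26,0,0,0,0.08
"FP",0,-0.15,0,0.12,0,0.1,0,0,0,0,0.1
"MOF",0,0.14,0.12,0,0.3,0,0.04,0.1,0,0,0.06
"RAC",0.38,0,0,0.3,0,0.17,0.09,0,0,0,0.06
"RMF",0,0.36,0.1,0,0.17,0,0.34,0,0.12,0,0.08
"SFG",0.14,0.26,0,0.04,0.09,0.34,0,0.16,0,0,0.1
"STG",0,0,0,0.1,0,0,0.16,0,0.32,0.52,0.08
"SMG",0.05,0,0,0,0,0.12,0,0.32,0,0.2,0.06
"TTG",0.08,0,0,0,0,0,0,0.52,0.2,0,0.05
"Age",0.06,0.08,0.1,0.06,0.06,0.08,0.1,0.08,0.06,0.05,0
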