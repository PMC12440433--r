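"subject","manual"
"patient_1",119.5
"patient_2",91
"patient_3",133
"patient_4",70.6
"patient_5",88.6
"patient_6",106.5
"patient_7",39.1
"patient_8",80
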