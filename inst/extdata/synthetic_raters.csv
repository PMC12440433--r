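"subject","rater_1","rater_2","rater_3","rater_4","rater_5","rater_6","rater_7","rater_8"
"patient_1",120.8,115.6,124.4,114.5,120.5,127.5,118.5,120.9
"patient_2",82,75.7,87.7,76.7,79.9,85.6,72.1,79.2
"patient_3",129,126.7,126.3,132.5,133.2,131.4,130.8,133.9
"patient_4",68.5,62.1,60.8,66.4,66.3,73.8,59.5,68.6
"patient_5",85.6,74.5,82.4,81.4,84.9,90.3,85.1,84.2
"patient_6",104.4,102.3,111.3,106,109.8,110.1,96.6,103.2
"patient_7",38.7,34.7,37.5,40.3,38.2,39.6,35.3,30.5
"patient_8",77.7,82.3,79.3,80.7,76,78.1,70.4,76.2
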