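# fps=30
# width=480
# height=480
# n_frames=21
# source=synthetic:shoulder_abduction:right:seed20
frame,joint,x,y,confidence
0,right_elbow,239.855560,240.109517,1.000000
0,right_hip,239.125677,281.913834,1.000000
0,right_shoulder,241.162685,160.188540,1.000000
0,right_wrist,240.555882,310.685732,1.000000
1,right_elbow,244.479437,239.801730,1.000000
1,right_hip,241.196331,279.523402,1.000000
1,right_shoulder,239.414076,159.362225,1.000000
1,right_wrist,246.675734,308.045611,1.000000
2,right_elbow,254.954330,238.224871,1.000000
2,right_hip,238.338800,279.616625,1.000000
2,right_shoulder,241.785465,159.964150,1.000000
2,right_wrist,266.298455,306.805230,1.000000
3,right_elbow,270.594103,234.369268,1.000000
3,right_hip,241.165212,281.074709,1.000000
3,right_shoulder,238.667406,160.112196,1.000000
3,right_wrist,297.835998,297.413542,1.000000
4,right_elbow,287.785328,221.522312,1.000000
4,right_hip,238.930338,279.142760,1.000000
4,right_shoulder,239.553433,161.210941,1.000000
4,right_wrist,333.239485,277.097319,1.000000
5,right_elbow,304.936004,206.732752,1.000000
5,right_hip,240.908884,280.818197,1.000000
5,right_shoulder,240.569606,161.440405,1.000000
5,right_wrist,363.754668,247.206601,1.000000
6,right_elbow,314.936067,186.449618,1.000000
6,right_hip,238.682493,278.370390,1.000000
6,right_shoulder,237.110282,162.208443,1.000000
6,right_wrist,383.681431,204.861004,1.000000
7,right_elbow,317.438398,162.778569,1.000000
7,right_hip,240.655430,281.154831,1.000000
7,right_shoulder,239.130982,158.031974,1.000000
7,right_wrist,389.455630,168.661388,1.000000
8,right_elbow,318.290276,145.251337,1.000000
8,right_hip,239.339628,280.467177,1.000000
8,right_shoulder,239.538297,160.558454,1.000000
8,right_wrist,389.044032,133.744892,1.000000
9,right_elbow,316.161185,135.606135,1.000000
9,right_hip,240.991581,279.632506,1.000000
9,right_shoulder,239.444459,159.783488,1.000000
9,right_wrist,383.176889,114.786770,1.000000
10,right_elbow,316.765555,131.707475,1.000000
10,right_hip,239.316776,279.854368,1.000000
10,right_shoulder,239.979865,159.932222,1.000000
10,right_wrist,381.144233,108.031248,1.000000
11,right_elbow,317.933640,134.733425,1.000000
11,right_hip,241.121321,280.283215,1.000000
11,right_shoulder,239.849618,160.266328,1.000000
11,right_wrist,384.543012,115.668855,1.000000
12,right_elbow,320.012236,148.718005,1.000000
12,right_hip,240.388551,281.552001,1.000000
12,right_shoulder,239.371873,161.285823,1.000000
12,right_wrist,388.675149,134.160915,1.000000
13,right_elbow,318.815693,163.649434,1.000000
13,right_hip,239.849233,281.037089,1.000000
13,right_shoulder,241.323221,161.101062,1.000000
13,right_wrist,389.893141,167.919152,1.000000
14,right_elbow,314.222161,184.351689,1.000000
14,right_hip,239.534023,280.330590,1.000000
14,right_shoulder,238.478649,159.404486,1.000000
14,right_wrist,383.984494,206.048604,1.000000
15,right_elbow,304.618585,206.640456,1.000000
15,right_hip,238.639484,281.328013,1.000000
15,right_shoulder,239.562572,160.155158,1.000000
15,right_wrist,362.464687,245.684997,1.000000
16,right_elbow,290.502960,223.315004,1.000000
16,right_hip,239.970414,280.334102,1.000000
16,right_shoulder,240.970578,160.548043,1.000000
16,right_wrist,331.539351,278.485372,1.000000
17,right_elbow,270.924024,234.869563,1.000000
17,right_hip,239.759233,280.969427,1.000000
17,right_shoulder,240.028223,159.774394,1.000000
17,right_wrist,298.176763,299.807998,1.000000
18,right_elbow,255.007905,240.281833,1.000000
18,right_hip,241.921899,278.206981,1.000000
18,right_shoulder,239.914218,161.217116,1.000000
18,right_wrist,267.404510,307.240033,1.000000
19,right_elbow,242.938724,240.723551,1.000000
19,right_hip,240.097136,279.643294,1.000000
19,right_shoulder,240.389214,160.700920,1.000000
19,right_wrist,246.975327,309.917248,1.000000
20,right_elbow,238.457432,240.366311,1.000000
20,right_hip,240.092219,280.733141,1.000000
20,right_shoulder,240.236687,160.911970,1.000000
20,right_wrist,239.615184,310.215796,1.000000
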