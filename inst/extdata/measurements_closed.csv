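"device","scenario","ach","point","x_m","y_m","z_m","concentration_bq_m3"
"AlphaGUARD","closed",1,"A",2.9,0.1,0.2,93
"AlphaGUARD","closed",1,"B",0.1,0.1,0.2,109
"AlphaGUARD","closed",1,"C",0.1,3.9,0.2,74
"AlphaGUARD","closed",1,"D",2.9,3.9,0.2,63
"AlphaGUARD","closed",1,"Center",1.5,2,0.2,91.5
"RAD7","closed",1,"A",2.9,0.1,0.2,120
"RAD7","closed",1,"B",0.1,0.1,0.2,99
"RAD7","closed",1,"C",0.1,3.9,0.2,82
"RAD7","closed",1,"D",2.9,3.9,0.2,66
"RAD7","closed",1,"Center",1.5,2,0.2,95.8
"Raduet","closed",1,"A",2.9,0.1,0.2,88
"Raduet","closed",1,"B",0.1,0.1,0.2,79
"Raduet","closed",1,"C",0.1,3.9,0.2,58
"Raduet","closed",1,"D",2.9,3.9,0.2,65
"NRPB","closed",1,"A",2.9,0.1,0.2,77
"NRPB","closed",1,"B",0.1,0.1,0.2,65
"NRPB","closed",1,"C",0.1,3.9,0.2,72
"NRPB","closed",1,"D",2.9,3.9,0.2,59
"Simulation","closed",1,"A",2.9,0.1,0.2,224.43
"Simulation","closed",1,"B",0.1,0.1,0.2,133.41
"Simulation","closed",1,"C",0.1,3.9,0.2,68.57
"Simulation","closed",1,"D",2.9,3.9,0.2,54.42
"Simulation","closed",1,"Center",1.5,2,0.2,82.35
"AlphaGUARD","closed",1,"A",2.9,0.1,1,110
"AlphaGUARD","closed",1,"B",0.1,0.1,1,108
"AlphaGUARD","closed",1,"C",0.1,3.9,1,61
"AlphaGUARD","closed",1,"D",2.9,3.9,1,63
"AlphaGUARD","closed",1,"Center",1.5,2,1,84.6
"RAD7","closed",1,"A",2.9,0.1,1,119
"RAD7","closed",1,"B",0.1,0.1,1,105
"RAD7","closed",1,"C",0.1,3.9,1,68
"RAD7","closed",1,"D",2.9,3.9,1,61
"RAD7","closed",1,"Center",1.5,2,1,77.1
"Raduet","closed",1,"A",2.9,0.1,1,89
"Raduet","closed",1,"B",0.1,0.1,1,92
"Raduet","closed",1,"C",0.1,3.9,1,66
"Raduet","closed",1,"D",2.9,3.9,1,74
"NRPB","closed",1,"A",2.9,0.1,1,76
"NRPB","closed",1,"B",0.1,0.1,1,66
"NRPB","closed",1,"C",0.1,3.9,1,58
"NRPB","closed",1,"D",2.9,3.9,1,63
"Simulation","closed",1,"A",2.9,0.1,1,170.7
"Simulation","closed",1,"B",0.1,0.1,1,140.18
"Simulation","closed",1,"C",0.1,3.9,1,51.33
"Simulation","closed",1,"D",2.9,3.9,1,45.3
"Simulation","closed",1,"Center",1.5,2,1,65.59
"Raduet","closed",1,"A",2.9,0.1,1.8,75
"Raduet","closed",1,"B",0.1,0.1,1.8,95
"Raduet","closed",1,"C",0.1,3.9,1.8,64
"Raduet","closed",1,"D",2.9,3.9,1.8,57
"NRPB","closed",1,"A",2.9,0.1,1.8,77
"NRPB","closed",1,"B",0.1,0.1,1.8,80
"NRPB","closed",1,"C",0.1,3.9,1.8,58
"NRPB","closed",1,"D",2.9,3.9,1.8,66
"Simulation","closed",1,"A",2.9,0.1,1.8,110.12
"Simulation","closed",1,"B",0.1,0.1,1.8,121.21
"Simulation","closed",1,"C",0.1,3.9,1.8,52.3
"Simulation","closed",1,"D",2.9,3.9,1.8,46.23
"Simulation","closed",1,"Center",1.5,2,1.8,59.17
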