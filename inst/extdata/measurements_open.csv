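"device","scenario","ach","point","x_m","y_m","z_m","concentration_bq_m3"
"AlphaGUARD","open",1,"A",2.9,0.1,0.2,119
"AlphaGUARD","open",1,"B",0.1,0.1,0.2,112
"AlphaGUARD","open",1,"C",0.1,3.9,0.2,81
"AlphaGUARD","open",1,"D",2.9,3.9,0.2,58
"AlphaGUARD","open",1,"Center",1.5,2,0.2,84
"RAD7","open",1,"A",2.9,0.1,0.2,110
"RAD7","open",1,"B",0.1,0.1,0.2,103
"RAD7","open",1,"C",0.1,3.9,0.2,84
"RAD7","open",1,"D",2.9,3.9,0.2,51
"RAD7","open",1,"Center",1.5,2,0.2,89
"Raduet","open",1,"A",2.9,0.1,0.2,88
"Raduet","open",1,"B",0.1,0.1,0.2,73
"Raduet","open",1,"C",0.1,3.9,0.2,66
"Raduet","open",1,"D",2.9,3.9,0.2,62
"NRPB","open",1,"A",2.9,0.1,0.2,74
"NRPB","open",1,"B",0.1,0.1,0.2,60
"NRPB","open",1,"C",0.1,3.9,0.2,69
"NRPB","open",1,"D",2.9,3.9,0.2,55
"Simulation","open",1,"A",2.9,0.1,0.2,163
"Simulation","open",1,"B",0.1,0.1,0.2,115
"Simulation","open",1,"C",0.1,3.9,0.2,65
"Simulation","open",1,"D",2.9,3.9,0.2,46
"Simulation","open",1,"Center",1.5,2,0.2,76
"AlphaGUARD","open",1,"A",2.9,0.1,1,92
"AlphaGUARD","open",1,"B",0.1,0.1,1,102
"AlphaGUARD","open",1,"C",0.1,3.9,1,67
"AlphaGUARD","open",1,"D",2.9,3.9,1,55
"AlphaGUARD","open",1,"Center",1.5,2,1,70
"RAD7","open",1,"A",2.9,0.1,1,109
"RAD7","open",1,"B",0.1,0.1,1,93
"RAD7","open",1,"C",0.1,3.9,1,71
"RAD7","open",1,"D",2.9,3.9,1,58
"RAD7","open",1,"Center",1.5,2,1,74
"Raduet","open",1,"A",2.9,0.1,1,66
"Raduet","open",1,"B",0.1,0.1,1,83
"Raduet","open",1,"C",0.1,3.9,1,61
"Raduet","open",1,"D",2.9,3.9,1,63
"NRPB","open",1,"A",2.9,0.1,1,71
"NRPB","open",1,"B",0.1,0.1,1,69
"NRPB","open",1,"C",0.1,3.9,1,59
"NRPB","open",1,"D",2.9,3.9,1,56
"Simulation","open",1,"A",2.9,0.1,1,154
"Simulation","open",1,"B",0.1,0.1,1,98
"Simulation","open",1,"C",0.1,3.9,1,50
"Simulation","open",1,"D",2.9,3.9,1,52
"Simulation","open",1,"Center",1.5,2,1,57
"Raduet","open",1,"A",2.9,0.1,1.8,65
"Raduet","open",1,"B",0.1,0.1,1.8,68
"Raduet","open",1,"C",0.1,3.9,1.8,55
"Raduet","open",1,"D",2.9,3.9,1.8,60
"NRPB","open",1,"A",2.9,0.1,1.8,63
"NRPB","open",1,"B",0.1,0.1,1.8,58
"NRPB","open",1,"C",0.1,3.9,1.8,60
"NRPB","open",1,"D",2.9,3.9,1.8,55
"Simulation","open",1,"A",2.9,0.1,1.8,199
"Simulation","open",1,"B",0.1,0.1,1.8,117
"Simulation","open",1,"C",0.1,3.9,1.8,49
"Simulation","open",1,"D",2.9,3.9,1.8,50
"Simulation","open",1,"Center",1.5,2,1.8,61
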