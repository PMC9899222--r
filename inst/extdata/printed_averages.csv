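"scenario","z_m","device","average_bq_m3"
"open",0.2,"AlphaGUARD",91
"open",0.2,"RAD7",87
"open",0.2,"Raduet",72
"open",0.2,"NRPB",65
"open",0.2,"Simulation",93
"open",1,"AlphaGUARD",77
"open",1,"RAD7",81
"open",1,"Raduet",68
"open",1,"NRPB",64
"open",1,"Simulation",82
"open",1.8,"Raduet",62
"open",1.8,"NRPB",59
"open",1.8,"Simulation",95
"closed",0.2,"AlphaGUARD",86
"closed",0.2,"RAD7",92
"closed",0.2,"Raduet",73
"closed",0.2,"NRPB",68
"closed",0.2,"Simulation",112
"closed",1,"AlphaGUARD",85
"closed",1,"RAD7",86
"closed",1,"Raduet",80
"closed",1,"NRPB",65
"closed",1,"Simulation",95
"closed",1.8,"Raduet",73
"closed",1.8,"NRPB",69
"closed",1.8,"Simulation",79
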