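"pair_id","round_index","condition","winner","agreement","channel","mean_loudness","mean_duration","n_whistles","mean_turn_gap","overlap_prop","dur_accent","loud_accent"
"fix01",0,"non_competitive",NA,NA,"A",0.09359148,0.29386624,25,2.271418,0.04,0.43581719,0.08132987
"fix01",0,"non_competitive",NA,NA,"B",0.09583506,0.29478547,17,2.217081,0,0.11890972,0.08586297
"fix01",1,"competitive","B",TRUE,"A",0.13297661,0.39068689,18,0.794353,0,0.0865714,0.09513045
"fix01",1,"competitive","B",TRUE,"B",0.13368925,0.38488356,16,0.24247167,0,0.32598995,0.02059454
"fix01",2,"competitive","A",TRUE,"A",0.16785877,0.45401092,13,1.08222167,0,0.0509685,0.16580447
"fix01",2,"competitive","A",TRUE,"B",0.13622056,0.38484081,16,0.575316,0.0625,0.25586031,0.0243622
"fix01",3,"competitive","A",TRUE,"A",0.1438356,0.31836213,15,1.007648,0,0.19640737,0.0245621
"fix01",3,"competitive","A",TRUE,"B",0.11832367,0.34528892,12,2.012709,0,0.22267333,-0.07688629
"fix01",4,"non_competitive",NA,NA,"A",0.13430406,0.22559412,17,2.071266,0.05882353,-0.00603542,0.14040523
"fix01",4,"non_competitive",NA,NA,"B",0.11812535,0.25364225,20,1.60260667,0,0.21104332,0.12661188
"fix02",0,"non_competitive",NA,NA,"A",0.08004663,0.23630042,19,1.348632,0,0.1548639,-0.06390989
"fix02",0,"non_competitive",NA,NA,"B",0.11589727,0.25007409,22,2.49095725,0,0.05606288,0.16324636
"fix02",1,"competitive","B",TRUE,"A",0.13252136,0.35274671,14,1.791618,0,0.28203364,0.01889097
"fix02",1,"competitive","B",TRUE,"B",0.13156362,0.40130169,13,0.900899,0,0.23680467,0.05458178
"fix02",2,"competitive","A",TRUE,"A",0.12160179,0.4096605,14,1.207388,0,0.3136405,0.01836025
"fix02",2,"competitive","A",TRUE,"B",0.12719827,0.34388864,11,1.833198,0,-0.01956855,0.04618988
"fix02",3,"competitive",NA,FALSE,"A",0.12549114,0.34171843,14,1.361482,0.07142857,0.13361783,0.14424533
"fix02",3,"competitive",NA,FALSE,"B",0.12032407,0.43967614,14,1.0641965,0,0.30056583,0.002804
"fix02",4,"non_competitive",NA,NA,"A",0.09175782,0.28580035,17,1.07764333,0,0.18090212,0.01499463
"fix02",4,"non_competitive",NA,NA,"B",0.10822624,0.27696386,21,1.77079767,0,0.24677162,0.05693262
"fix03",0,"non_competitive",NA,NA,"A",0.10488582,0.26642077,22,1.1024135,0,0.08653494,0.0923671
"fix03",0,"non_competitive",NA,NA,"B",0.10259356,0.2734316,25,1.11937233,0,0.10976523,0.10626081
"fix03",1,"competitive",NA,FALSE,"A",0.14010229,0.349058,17,0.600988,0,0.02328489,-0.05176454
"fix03",1,"competitive",NA,FALSE,"B",0.11646523,0.40520908,13,1.21922233,0,0.13413061,-0.06671578
"fix03",2,"competitive","B",FALSE,"A",0.1357525,0.34559142,12,2.026082,0,0.06539744,0.04200178
"fix03",2,"competitive","B",FALSE,"B",0.12578365,0.35009718,17,0.36009267,0,0.16466217,0.10237372
"fix03",3,"competitive","B",TRUE,"A",0.12916857,0.36847479,14,0.766214,0,0.19080767,-0.00334237
"fix03",3,"competitive","B",TRUE,"B",0.11322108,0.31537533,12,1.8607155,0,-0.0066586,-0.0463495
"fix03",4,"non_competitive",NA,NA,"A",0.12236765,0.18890785,20,1.08756367,0,-0.1387652,0.1141209
"fix03",4,"non_competitive",NA,NA,"B",0.08733948,0.24976076,29,1.063694,0,0.11262742,0.06536344
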