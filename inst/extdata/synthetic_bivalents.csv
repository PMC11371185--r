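genotype,cell_id,pair_index,stage,config,n_class1_foci,focus_positions,n_chiasmata,n_labeled_chiasmata,length_um
AACC_wt,cell0001,0,diakinesis,ring,3,0.055500;0.426507;0.887798,3,3,
AACC_wt,cell0001,1,diakinesis,ring,2,0.123886;0.710347,2,2,
AACC_wt,cell0001,2,diakinesis,ring,2,0.001756;0.729311,2,2,
AACC_wt,cell0001,3,diakinesis,ring,1,0.678635,3,1,
AACC_wt,cell0001,4,diakinesis,rod,1,0.233447,1,1,
AACC_wt,cell0001,5,diakinesis,rod,1,0.484887,3,1,
AACC_wt,cell0001,6,diakinesis,ring,3,0.148863;0.387749;0.876988,4,3,
AACC_wt,cell0001,7,diakinesis,ring,1,0.447547,2,1,
AACC_wt,cell0001,8,diakinesis,rod,1,0.941157,1,1,
AACC_wt,cell0001,9,diakinesis,rod,1,0.490881,1,1,
AACC_wt,cell0001,10,diakinesis,rod,1,0.477007,2,1,
AACC_wt,cell0001,11,diakinesis,ring,2,0.440984;0.836742,2,2,
AACC_wt,cell0001,12,diakinesis,rod,1,0.619092,3,1,
AACC_wt,cell0001,13,diakinesis,rod,1,0.601763,1,1,
AACC_wt,cell0001,14,diakinesis,rod,1,0.692671,3,1,
AACC_wt,cell0001,15,diakinesis,ring,2,0.257136;0.553341,3,2,
AACC_wt,cell0001,16,diakinesis,ring,2,0.090132;0.543545,2,2,
AACC_wt,cell0001,17,diakinesis,ring,2,0.134262;0.523089,2,2,
AACC_wt,cell0001,18,diakinesis,rod,1,0.526759,2,1,
AACC_wt,cell0002,0,diakinesis,ring,2,0.216398;0.789061,4,2,
AACC_wt,cell0002,1,diakinesis,rod,1,0.598970,2,1,
AACC_wt,cell0002,2,diakinesis,rod,2,0.029153;0.389387,2,2,
AACC_wt,cell0002,3,diakinesis,rod,1,0.452217,1,1,
AACC_wt,cell0002,4,diakinesis,rod,1,0.650479,3,1,
AACC_wt,cell0002,5,diakinesis,ring,2,0.222262;0.669551,3,2,
AACC_wt,cell0002,6,diakinesis,ring,2,0.077347;0.536842,2,2,
AACC_wt,cell0002,7,diakinesis,ring,2,0.382776;0.772573,3,2,
AACC_wt,cell0002,8,diakinesis,ring,2,0.162905;0.456416,3,2,
AACC_wt,cell0002,9,diakinesis,rod,1,0.746514,1,1,
AACC_wt,cell0002,10,diakinesis,rod,1,0.577680,1,1,
AACC_wt,cell0002,11,diakinesis,ring,1,0.443224,2,1,
AACC_wt,cell0002,12,diakinesis,ring,2,0.204254;0.670644,2,2,
AACC_wt,cell0002,13,diakinesis,ring,2,0.432914;0.849596,2,2,
AACC_wt,cell0002,14,diakinesis,ring,2,0.049577;0.651952,2,2,
AACC_wt,cell0002,15,diakinesis,ring,2,0.281897;0.793251,2,2,
AACC_wt,cell0002,16,diakinesis,rod,1,0.374754,1,1,
AACC_wt,cell0002,17,diakinesis,ring,2,0.058658;0.854769,3,2,
AACC_wt,cell0002,18,diakinesis,rod,2,0.038532;0.374998,2,2,
AACC_wt,cell0003,0,diakinesis,rod,1,0.286241,1,1,
AACC_wt,cell0003,1,diakinesis,ring,2,0.211263;0.818400,2,2,
AACC_wt,cell0003,2,diakinesis,ring,2,0.005485;0.563384,3,2,
AACC_wt,cell0003,3,diakinesis,rod,1,0.502371,2,1,
AACC_wt,cell0003,4,diakinesis,rod,1,0.912632,1,1,
AACC_wt,cell0003,5,diakinesis,ring,2,0.197742;0.777318,3,2,
AACC_wt,cell0003,6,diakinesis,ring,2,0.014992;0.557168,2,2,
AACC_wt,cell0003,7,diakinesis,ring,2,0.198762;0.968031,2,2,
AACC_wt,cell0003,8,diakinesis,rod,1,0.293430,1,1,
AACC_wt,cell0003,9,diakinesis,ring,1,0.836162,2,1,
AACC_wt,cell0003,10,diakinesis,rod,1,0.635588,1,1,
AACC_wt,cell0003,11,diakinesis,rod,1,0.176814,1,1,
AACC_wt,cell0003,12,diakinesis,rod,1,0.572951,1,1,
AACC_wt,cell0003,13,diakinesis,rod,1,0.069000,1,1,
AACC_wt,cell0003,14,diakinesis,ring,1,0.821615,2,1,
AACC_wt,cell0003,15,diakinesis,ring,2,0.230382;0.672187,2,2,
AACC_wt,cell0003,16,diakinesis,rod,1,0.110024,2,1,
AACC_wt,cell0003,17,diakinesis,ring,2,0.121361;0.843036,2,2,
AACC_wt,cell0003,18,diakinesis,ring,2,0.202181;0.797797,3,2,
aaCc,cell0001,0,diakinesis,rod,2,0.612036;0.790652,2,2,
aaCc,cell0001,1,diakinesis,ring,1,0.711240,3,1,
aaCc,cell0001,2,diakinesis,rod,4,0.498721;0.559083;0.616329;0.880085,4,4,
aaCc,cell0001,3,diakinesis,rod,1,0.631653,2,1,
aaCc,cell0001,4,diakinesis,ring,2,0.278167;0.541799,2,2,
aaCc,cell0001,5,diakinesis,rod,0,,1,0,
aaCc,cell0001,6,diakinesis,ring,2,0.020213;0.919215,3,2,
aaCc,cell0001,7,diakinesis,ring,2,0.051029;0.459438,2,2,
aaCc,cell0001,8,diakinesis,rod,1,0.979757,1,1,
aaCc,cell0001,9,diakinesis,rod,1,0.592708,1,1,
aaCc,cell0001,10,diakinesis,rod,1,0.258612,1,1,
aaCc,cell0001,11,diakinesis,ring,2,0.192045;0.934317,3,2,
aaCc,cell0001,12,diakinesis,rod,1,0.678123,1,1,
aaCc,cell0001,13,diakinesis,rod,3,0.585131;0.775896;0.915109,3,3,
aaCc,cell0001,14,diakinesis,ring,2,0.194735;0.825058,2,2,
aaCc,cell0001,15,diakinesis,univalent_pair,0,,0,0,
aaCc,cell0001,16,diakinesis,ring,3,0.261718;0.633759;0.749184,4,3,
aaCc,cell0001,17,diakinesis,rod,2,0.103045;0.335486,2,2,
aaCc,cell0001,18,diakinesis,rod,1,0.966874,1,1,
aaCc,cell0002,0,diakinesis,univalent_pair,0,,0,0,
aaCc,cell0002,1,diakinesis,rod,1,0.880902,1,1,
aaCc,cell0002,2,diakinesis,rod,0,,1,0,
aaCc,cell0002,3,diakinesis,ring,2,0.156167;0.500218,2,2,
aaCc,cell0002,4,diakinesis,rod,1,0.234036,1,1,
aaCc,cell0002,5,diakinesis,ring,1,0.607592,2,1,
aaCc,cell0002,6,diakinesis,ring,4,0.652382;0.718656;0.841291;0.842928,5,4,
aaCc,cell0002,7,diakinesis,rod,2,0.558684;0.867491,3,2,
aaCc,cell0002,8,diakinesis,ring,4,0.178028;0.366042;0.376321;0.895368,4,4,
aaCc,cell0002,9,diakinesis,ring,2,0.336020;0.483017,3,2,
aaCc,cell0002,10,diakinesis,rod,1,0.393382,1,1,
aaCc,cell0002,11,diakinesis,rod,4,0.087791;0.113980;0.190883;0.382782,4,4,
aaCc,cell0002,12,diakinesis,ring,2,0.002118;0.847339,2,2,
aaCc,cell0002,13,diakinesis,ring,4,0.238069;0.620308;0.710543;0.824291,4,4,
aaCc,cell0002,14,diakinesis,ring,0,,3,0,
aaCc,cell0002,15,diakinesis,univalent_pair,0,,0,0,
aaCc,cell0002,16,diakinesis,rod,2,0.521122;0.632494,2,2,
aaCc,cell0002,17,diakinesis,ring,3,0.065663;0.456427;0.947238,3,3,
aaCc,cell0002,18,diakinesis,rod,2,0.540660;0.818987,2,2,
aaCc,cell0003,0,diakinesis,rod,2,0.036440;0.085881,3,2,
aaCc,cell0003,1,diakinesis,ring,2,0.106169;0.866810,3,2,
aaCc,cell0003,2,diakinesis,ring,3,0.099918;0.278086;0.586592,3,3,
aaCc,cell0003,3,diakinesis,ring,4,0.325209;0.505160;0.572162;0.835437,4,4,
aaCc,cell0003,4,diakinesis,rod,2,0.154366;0.205069,2,2,
aaCc,cell0003,5,diakinesis,rod,2,0.520217;0.705981,2,2,
aaCc,cell0003,6,diakinesis,rod,5,0.664832;0.692906;0.835026;0.886477;0.916393,5,5,
aaCc,cell0003,7,diakinesis,rod,2,0.661933;0.933987,2,2,
aaCc,cell0003,8,diakinesis,ring,6,0.076653;0.099595;0.241258;0.305620;0.319974;0.639302,7,6,
aaCc,cell0003,9,diakinesis,rod,1,0.273281,1,1,
aaCc,cell0003,10,diakinesis,rod,1,0.899684,1,1,
aaCc,cell0003,11,diakinesis,univalent_pair,0,,0,0,
aaCc,cell0003,12,diakinesis,rod,2,0.480439;0.967554,2,2,
aaCc,cell0003,13,diakinesis,rod,1,0.736307,1,1,
aaCc,cell0003,14,diakinesis,ring,1,0.053769,2,1,
aaCc,cell0003,15,diakinesis,rod,1,0.543683,1,1,
aaCc,cell0003,16,diakinesis,ring,4,0.099756;0.654915;0.687770;0.767483,4,4,
aaCc,cell0003,17,diakinesis,ring,2,0.048677;0.709181,2,2,
aaCc,cell0003,18,diakinesis,univalent_pair,0,,0,0,
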