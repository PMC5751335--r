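id,actual_pE,comfa_pred,comfa_resid,comsia_pred,comsia_resid,comfa_test,comsia_test
1b,1.4942,1.4542,0.04,1.4992,-0.01,FALSE,FALSE
2b,1.2655,1.2905,-0.03,1.2400,0.03,FALSE,TRUE
3b,1.1245,1.1260,0.00,1.1385,-0.01,TRUE,FALSE
4b,1.2946,1.2646,0.03,1.2956,0.00,FALSE,FALSE
5b,1.0394,1.0184,0.02,1.0454,-0.01,FALSE,FALSE
6b,0.9688,1.0188,-0.05,0.9578,0.01,FALSE,FALSE
7b,1.0321,1.1411,-0.11,1.4260,-0.39,FALSE,FALSE
8b,0.8410,1.1134,-0.27,0.8320,0.01,TRUE,FALSE
9b,0.1643,1.0641,-0.90,1.1240,-0.96,FALSE,FALSE
10b,1.4344,1.3964,0.04,1.4284,0.01,FALSE,FALSE
11b,1.2343,1.2393,-0.01,1.2373,0.00,FALSE,FALSE
12b,1.2569,1.2409,0.02,1.2539,0.00,FALSE,FALSE
13b,1.3818,1.4298,-0.05,1.3778,0.00,FALSE,FALSE
14b,1.3818,1.3958,-0.01,1.3738,0.01,FALSE,FALSE
15b,1.4942,1.5332,-0.04,1.5100,-0.02,FALSE,TRUE
16b,1.4891,1.4141,0.08,1.5071,-0.02,FALSE,FALSE
17b,1.5579,1.5627,0.00,1.6059,-0.05,TRUE,FALSE
18b,1.5260,1.4940,0.03,1.5890,-0.06,FALSE,TRUE
19b,1.5916,1.5956,0.00,1.5826,0.01,FALSE,FALSE
20b,1.8987,1.5444,0.35,1.7690,0.13,FALSE,TRUE
21b,1.5513,1.5693,-0.02,1.5760,-0.02,FALSE,TRUE
22b,1.5997,1.5977,0.00,1.5577,0.04,FALSE,FALSE
23b,1.3511,1.3751,-0.02,1.3671,-0.02,FALSE,FALSE
24b,1.5916,1.5526,0.04,1.5896,0.00,FALSE,FALSE
25b,1.3948,1.3858,0.01,1.5560,-0.16,FALSE,TRUE
26b,1.5997,1.3252,0.27,1.5887,0.01,FALSE,FALSE
6a,2.0000,1.4404,0.56,1.5060,0.49,FALSE,FALSE
8a,1.5490,1.5644,-0.02,1.5380,0.01,TRUE,FALSE
10a,1.4967,1.5217,-0.03,1.5030,-0.01,FALSE,TRUE
12a,1.5165,1.5136,0.00,1.5045,0.01,TRUE,FALSE
15a,1.2612,1.2562,0.01,1.2652,0.00,FALSE,FALSE
21a,1.6812,1.3303,0.35,1.6852,0.00,FALSE,FALSE
22a,1.1750,1.2050,-0.03,1.1850,-0.01,FALSE,FALSE
23a,0.9425,0.9105,0.03,0.9510,-0.01,FALSE,TRUE
24a,1.1803,1.1804,0.00,1.1733,0.01,TRUE,FALSE
25a,0.8740,1.1388,-0.26,1.1280,-0.25,TRUE,FALSE
26a,0.9602,0.9132,0.05,0.9732,-0.01,FALSE,FALSE
27a,0.9855,0.9785,0.01,0.9785,0.01,FALSE,FALSE
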