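id,actual_pE,comfa_pred,comfa_resid,comsia_pred,comsia_resid,comfa_test,comsia_test
1a,1.5318,1.4708,0.06,1.5338,0.00,FALSE,FALSE
2a,1.0056,0.9666,0.04,1.0086,0.00,FALSE,FALSE
3a,1.4790,1.5260,-0.05,1.4780,0.00,FALSE,FALSE
4a,1.3336,1.2516,0.08,1.3326,0.00,FALSE,FALSE
5a,1.0580,0.9970,0.06,1.0570,0.00,FALSE,FALSE
6a,2.0000,1.6380,0.36,1.9990,0.00,TRUE,FALSE
7a,1.5544,1.4410,0.11,1.6120,-0.06,TRUE,TRUE
8a,0.8617,1.0327,-0.17,1.1680,-0.31,FALSE,TRUE
9a,1.7667,1.7127,0.05,1.7687,0.00,FALSE,FALSE
10a,1.3688,1.2908,0.08,1.3730,0.00,FALSE,TRUE
11a,1.7263,1.7293,0.00,1.7243,0.00,FALSE,FALSE
12a,0.8125,1.4180,-0.61,1.3220,-0.51,FALSE,TRUE
13a,1.4901,1.3231,0.17,1.4941,0.00,FALSE,FALSE
14a,1.2470,1.2600,-0.01,1.2474,0.00,TRUE,FALSE
15a,0.9943,1.1333,-0.14,0.9953,0.00,FALSE,FALSE
16a,1.3590,1.5220,-0.16,1.3670,-0.01,FALSE,FALSE
17a,1.2275,1.1835,0.04,1.2245,0.00,FALSE,FALSE
18a,1.7046,1.4880,0.22,1.6996,0.01,TRUE,FALSE
19a,1.3230,1.2650,0.06,1.3420,-0.02,FALSE,TRUE
20a,1.3590,1.3170,0.04,1.3588,0.00,FALSE,FALSE
21a,1.7068,1.7398,-0.03,1.7058,0.00,FALSE,FALSE
22a,1.1854,1.1804,0.01,1.1940,-0.01,FALSE,TRUE
23a,1.4013,1.3800,0.02,1.4033,0.00,TRUE,FALSE
24a,1.0773,0.9713,0.11,1.0753,0.00,FALSE,FALSE
25a,0.8295,1.0695,-0.24,0.8265,0.00,FALSE,FALSE
26a,0.9708,0.9068,0.06,0.9706,0.00,FALSE,FALSE
27a,1.2779,1.2430,0.03,1.2749,0.00,TRUE,FALSE
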