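id,E_mm,pE_printed
1b,17.10,1.4942
2b,10.10,1.2655
3b,7.30,1.1245
4b,10.80,1.2946
5b,6.00,1.0394
6b,5.10,0.9688
7b,5.90,1.0321
8b,3.80,0.8410
9b,0.80,0.1643
10b,14.90,1.4344
11b,9.40,1.2343
12b,9.90,1.2569
13b,13.20,1.3818
14b,13.20,1.3818
15b,17.10,1.4942
16b,16.90,1.4891
17b,19.80,1.5579
18b,18.40,1.5260
19b,21.40,1.5916
20b,43.40,1.8987
21b,19.50,1.5513
22b,21.80,1.5997
23b,12.30,1.3511
24b,21.40,1.5916
25b,13.60,1.3948
26b,21.80,1.5997
6a,54.80,2.0000
8a,19.40,1.5490
10a,17.20,1.4967
12a,18.00,1.5165
15a,10.00,1.2612
21a,26.30,1.6812
22a,8.20,1.1750
23a,4.80,0.9425
24a,8.30,1.1803
25a,4.10,0.8740
26a,5.00,0.9602
27a,5.30,0.9855
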