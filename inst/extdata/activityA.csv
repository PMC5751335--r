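id,E_mm,pE_printed
1a,13.10,1.5318
2a,3.90,1.0056
3a,11.60,1.4790
4a,8.30,1.3336
5a,4.40,1.0580
6a,38.50,2.0000
7a,13.80,1.5544
8a,2.80,0.8617
9a,22.50,1.7667
10a,9.00,1.3688
11a,20.50,1.7263
12a,2.50,0.8125
13a,11.90,1.4901
14a,6.80,1.2470
15a,3.80,0.9943
16a,8.80,1.3590
17a,6.50,1.2275
18a,19.50,1.7046
19a,8.10,1.3230
20a,8.80,1.3590
21a,19.60,1.7068
22a,5.90,1.1854
23a,9.70,1.4013
24a,4.60,1.0773
25a,2.60,0.8295
26a,3.60,0.9708
27a,7.30,1.2779
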