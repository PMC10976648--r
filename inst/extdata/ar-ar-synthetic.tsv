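# pair: Ar Ar
# source: synthetic LJ12-6 (epsilon=0.996, sigma=3.405) noise_sd=0.01 seed=42
2.2	698.003975887
2.3	399.612769662
2.4	232.479068774
2.5	136.921375046
2.6	81.3062356953
2.7	48.442690683
2.8	28.8008944004
2.9	16.9101105186
3	9.71134148713
3.1	5.28860093726
3.2	2.62361194136
3.3	1.0168841699
3.4	0.0217062889887
3.5	-0.516858451553
3.6	-0.811527571871
3.7	-0.94366498586
3.8	-0.997607300191
3.9	-1.00957943036
4	-0.963502215949
4.1	-0.865066314963
4.2	-0.813063515555
4.3	-0.757878311561
4.4	-0.67361089546
4.5	-0.595249169699
4.6	-0.528597706455
4.7	-0.497039269924
4.8	-0.44554571502
4.9	-0.415708108673
5	-0.353139832361
5.1	-0.328006418115
5.2	-0.284741554164
5.3	-0.253388619083
5.4	-0.224323647878
5.5	-0.217768744524
5.6	-0.186100214076
5.7	-0.189982684832
5.8	-0.164267515284
5.9	-0.150271035137
6	-0.152777218978
6.1	-0.116508723926
6.2	-0.104253701991
6.3	-0.100441955536
6.4	-0.0807221768441
6.5	-0.0878927364192
6.6	-0.0873868630027
6.7	-0.063128606823
6.8	-0.0699252595016
6.9	-0.0422624985036
7	-0.0563910214796
7.1	-0.0413237090413
7.2	-0.0408505680014
7.3	-0.0484442933398
7.4	-0.0216960283963
7.5	-0.028151784881
7.6	-0.0310629094308
7.7	-0.0268022251642
7.8	-0.0205874271202
7.9	-0.0244801835273
8	-0.0534755625004
8.1	-0.0190141214138
8.2	-0.0239915547503
8.3	-0.0170484119689
8.4	-0.0117778187843
8.5	-0.00239758302237
8.6	-0.0225610759647
8.7	-0.00124190716929
8.8	-0.00996648458242
8.9	-0.00206919941542
9	-0.00244179096224
9.1	-0.00369507513821
9.2	-0.0206447549202
9.3	-0.0104755003947
9.4	-0.00274474278758
9.5	-0.0179638960028
9.6	-0.0133447127278
9.7	-0.00163012689556
9.8	0.000684965230214
9.9	-0.00194634730356
10	-0.0150570915836
10.1	-0.0168383852709
10.2	0.00962128108896
10.3	-0.00261394277061
10.4	-0.00401662074713
10.5	-0.00583683237571
10.6	-0.0163155836549
10.7	0.00198694315797
10.8	-0.00608028225269
10.9	-0.00552635364522
11	0.00583172496576
11.1	0.00490090932519
11.2	0.0107779722201
11.3	-0.00774180703176
11.4	0.00367675481504
11.5	0.0112285888838
11.6	-0.0136546967548
11.7	-0.0110269651332
11.8	-0.0136160703567
11.9	-0.0167773936179
12	-0.00127847246396
12.1	0.00455464540267
12.2	0.0101274886248
12.3	0.0086552721533
12.4	-0.0117393701374
12.5	0.0168578305176
12.6	-0.00821879758318
12.7	-0.000424100915792
12.8	-0.0056338228931
12.9	-0.00257040641003
13	0.000595987503202
13.1	-3.6565577002e-05
13.2	-0.00142433736002
13.3	-4.07484472356e-05
13.4	-0.00592655360933
13.5	-0.00606760501835
13.6	-0.017592019235
13.7	-0.00476218734175
13.8	-0.00602527450993
13.9	0.0261582346365
14	-0.0144456115336
14.1	0.000582572885244
14.2	-0.0156934485639
14.3	-0.0154303407328
14.4	0.000550764326906
14.5	-0.0106343370867
14.6	-0.000659192159541
14.7	-0.00489783784066
14.8	-0.00672744375028
14.9	-0.0208141173488
15	-0.0127925027772
15.1	0.0012714394887
15.2	0.00517281474947
15.3	-0.00541274602431
15.4	-0.000464793212675
15.5	0.0107812006269
15.6	0.0139678052604
15.7	-0.0113856895894
15.8	-0.00157225358062
15.9	0.0116307485955
16	-0.00506734697981
16.1	-0.000881168888248
16.2	-0.00120454747692
16.3	-0.00920781481107
16.4	-0.00476593809868
16.5	-0.000602118555377
16.6	-0.00443540461683
16.7	0.0108476454932
16.8	-0.00508607281073
16.9	-0.00459817531305
17	0.00671140829855
17.1	-0.0108120079015
17.2	-0.000646771514177
17.3	-0.0157470384144
17.4	0.011447976864
17.5	-0.00295261444463
17.6	-0.00488734593899
17.7	-0.0125844344832
17.8	-0.000272820751176
17.9	-0.00819157017328
18	-0.0055174671034
18.1	0.0127001765966
18.2	-0.00192609300363
18.3	-0.0108831332102
18.4	0.00147207705304
18.5	-0.00378225682185
18.6	0.00575019185153
18.7	0.0141790226397
18.8	-0.0100675491611
18.9	0.00441028439467
19	0.00071700729953
19.1	0.00882777427523
19.2	-0.00242171843643
19.3	0.00824605692272
19.4	-0.0175670245574
19.5	0.0167816611061
19.6	0.00853826477184
19.7	-0.00161398155044
19.8	-0.0145931145762
19.9	0.00633011171099
20	0.00473492529354
20.1	-0.000157709536559
20.2	0.0014231678406
20.3	-0.00592981268502
20.4	0.00360192201758
20.5	0.00286288881366
20.6	-0.00287384120377
20.7	-0.0134412873257
20.8	0.00693081673746
20.9	0.00546746966779
21	-0.00843545922684
21.1	-0.0160162406147
21.2	0.00198119473466
21.3	-0.00351736684424
21.4	0.00246147242061
21.5	-0.0130028861078
21.6	-0.00965283985756
21.7	0.010798284123
21.8	0.00397990259077
21.9	0.00580859574115
22	0.0180975223768
22.1	0.00123492221774
22.2	-0.0200611602608
22.3	0.00328728406989
22.4	0.0116641007035
22.5	0.0205475380421
22.6	-0.0138152138789
22.7	-0.0115539353894
22.8	-0.00710241250831
22.9	-0.010583610922
23	-0.00649937935727
23.1	-0.00189464413007
23.2	-0.012052039455
23.3	0.0203309171538
23.4	0.00103992734127
23.5	-0.000877945716169
23.6	0.00492025906253
23.7	0.000339114762869
23.8	-0.00135504341359
23.9	0.0147345599127
24	-0.00220279219996
24.1	-0.0128677116088
24.2	0.00382576695021
24.3	-0.0035452852466
24.4	-0.00524738345323
24.5	-0.0107100212929
24.6	0.00425564289063
24.7	-0.001767524788
24.8	0.00512998971638
24.9	-0.00236970369544
25	-0.00661046618139
25.1	0.0124775360252
25.2	-0.00274188181343
25.3	0.00945584461359
25.4	-0.0120389458651
25.5	-0.00468374379987
25.6	-0.00271557264729
25.7	-0.00393120277452
25.8	0.0134660177256
25.9	-0.000248216392939
26	0.00242215926583
26.1	-0.00944335867772
26.2	-0.00731136882899
26.3	0.00996192681081
26.4	0.0125664767669
26.5	0.012470708352
26.6	-0.0138238984118
26.7	0.0204824692342
26.8	0.0101519707128
26.9	-0.000283561909555
27	0.00702005132461
27.1	-0.0097295271841
27.2	-0.0109768947023
27.3	0.000475506123943
27.4	-0.0119996315025
27.5	0.00188583428807
27.6	0.0129630125646
27.7	-0.0103524821401
27.8	-0.0073978584558
27.9	0.000452475167204
28	-0.0101888458426
28.1	-0.00384545156317
28.2	0.00871520812357
28.3	0.00968336359684
28.4	0.00382663321888
28.5	-0.018527143113
28.6	-0.00055131289312
28.7	0.01063662175
28.8	0.00812106944667
28.9	-0.00191882171266
29	-0.0270097364608
29.1	0.000599441395968
29.2	0.00572750029421
29.3	0.000448222493644
29.4	0.00156451067389
29.5	0.00430623290438
29.6	-0.0039747288282
29.7	0.0130907357209
29.8	0.00469506808551
29.9	-0.012435392189
30	0.0138072374281
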