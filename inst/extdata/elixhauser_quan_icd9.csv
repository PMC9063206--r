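group_index,group,icd9_prefix
1,CongestiveHeartFailure,39891
1,CongestiveHeartFailure,40201
1,CongestiveHeartFailure,40211
1,CongestiveHeartFailure,40291
1,CongestiveHeartFailure,40401
1,CongestiveHeartFailure,40403
1,CongestiveHeartFailure,40411
1,CongestiveHeartFailure,40413
1,CongestiveHeartFailure,40491
1,CongestiveHeartFailure,40493
1,CongestiveHeartFailure,4254
1,CongestiveHeartFailure,4255
1,CongestiveHeartFailure,4256
1,CongestiveHeartFailure,4257
1,CongestiveHeartFailure,4258
1,CongestiveHeartFailure,4259
1,CongestiveHeartFailure,428
2,CardiacArrhythmias,4260
2,CardiacArrhythmias,42613
2,CardiacArrhythmias,4267
2,CardiacArrhythmias,4269
2,CardiacArrhythmias,42610
2,CardiacArrhythmias,42612
2,CardiacArrhythmias,4270
2,CardiacArrhythmias,4271
2,CardiacArrhythmias,4272
2,CardiacArrhythmias,4273
2,CardiacArrhythmias,4274
2,CardiacArrhythmias,4276
2,CardiacArrhythmias,4277
2,CardiacArrhythmias,4278
2,CardiacArrhythmias,4279
2,CardiacArrhythmias,7850
2,CardiacArrhythmias,99601
2,CardiacArrhythmias,99604
2,CardiacArrhythmias,V450
2,CardiacArrhythmias,V533
3,ValvularDisease,0932
3,ValvularDisease,394
3,ValvularDisease,395
3,ValvularDisease,396
3,ValvularDisease,397
3,ValvularDisease,424
3,ValvularDisease,7463
3,ValvularDisease,7464
3,ValvularDisease,7465
3,ValvularDisease,7466
3,ValvularDisease,V422
3,ValvularDisease,V433
4,PulmonaryCirculation,4150
4,PulmonaryCirculation,4151
4,PulmonaryCirculation,416
4,PulmonaryCirculation,4170
4,PulmonaryCirculation,4178
4,PulmonaryCirculation,4179
5,PeripheralVascular,0930
5,PeripheralVascular,4373
5,PeripheralVascular,440
5,PeripheralVascular,441
5,PeripheralVascular,4431
5,PeripheralVascular,4432
5,PeripheralVascular,4433
5,PeripheralVascular,4434
5,PeripheralVascular,4435
5,PeripheralVascular,4436
5,PeripheralVascular,4437
5,PeripheralVascular,4438
5,PeripheralVascular,4439
5,PeripheralVascular,4471
5,PeripheralVascular,5571
5,PeripheralVascular,5579
5,PeripheralVascular,V434
6,HypertensionUncomplicated,401
7,HypertensionComplicated,402
7,HypertensionComplicated,403
7,HypertensionComplicated,404
7,HypertensionComplicated,405
8,Paralysis,3341
8,Paralysis,342
8,Paralysis,343
8,Paralysis,3440
8,Paralysis,3441
8,Paralysis,3442
8,Paralysis,3443
8,Paralysis,3444
8,Paralysis,3445
8,Paralysis,3446
8,Paralysis,3449
9,OtherNeurological,3319
9,OtherNeurological,3320
9,OtherNeurological,3321
9,OtherNeurological,3334
9,OtherNeurological,3335
9,OtherNeurological,33392
9,OtherNeurological,334
9,OtherNeurological,335
9,OtherNeurological,3362
9,OtherNeurological,340
9,OtherNeurological,341
9,OtherNeurological,345
9,OtherNeurological,3481
9,OtherNeurological,3483
9,OtherNeurological,7803
9,OtherNeurological,7843
10,ChronicPulmonary,4168
10,ChronicPulmonary,4169
10,ChronicPulmonary,490
10,ChronicPulmonary,491
10,ChronicPulmonary,492
10,ChronicPulmonary,493
10,ChronicPulmonary,494
10,ChronicPulmonary,495
10,ChronicPulmonary,496
10,ChronicPulmonary,500
10,ChronicPulmonary,501
10,ChronicPulmonary,502
10,ChronicPulmonary,503
10,ChronicPulmonary,504
10,ChronicPulmonary,505
10,ChronicPulmonary,5064
10,ChronicPulmonary,5081
10,ChronicPulmonary,5088
11,DiabetesUncomplicated,2500
11,DiabetesUncomplicated,2501
11,DiabetesUncomplicated,2502
11,DiabetesUncomplicated,2503
12,DiabetesComplicated,2504
12,DiabetesComplicated,2505
12,DiabetesComplicated,2506
12,DiabetesComplicated,2507
12,DiabetesComplicated,2508
12,DiabetesComplicated,2509
13,Hypothyroidism,2409
13,Hypothyroidism,243
13,Hypothyroidism,2440
13,Hypothyroidism,2441
13,Hypothyroidism,2442
13,Hypothyroidism,2448
13,Hypothyroidism,2449
14,RenalFailure,40301
14,RenalFailure,40311
14,RenalFailure,40391
14,RenalFailure,40402
14,RenalFailure,40403
14,RenalFailure,40412
14,RenalFailure,40413
14,RenalFailure,40492
14,RenalFailure,40493
14,RenalFailure,585
14,RenalFailure,586
14,RenalFailure,5880
14,RenalFailure,V420
14,RenalFailure,V451
14,RenalFailure,V56
15,LiverDisease,07022
15,LiverDisease,07023
15,LiverDisease,07032
15,LiverDisease,07033
15,LiverDisease,07044
15,LiverDisease,07054
15,LiverDisease,0706
15,LiverDisease,0709
15,LiverDisease,4560
15,LiverDisease,4561
15,LiverDisease,4562
15,LiverDisease,570
15,LiverDisease,571
15,LiverDisease,5722
15,LiverDisease,5723
15,LiverDisease,5724
15,LiverDisease,5728
15,LiverDisease,5733
15,LiverDisease,5734
15,LiverDisease,5738
15,LiverDisease,5739
15,LiverDisease,V427
16,PepticUlcer,5317
16,PepticUlcer,5319
16,PepticUlcer,5327
16,PepticUlcer,5329
16,PepticUlcer,5337
16,PepticUlcer,5339
16,PepticUlcer,5347
16,PepticUlcer,5349
17,AIDSHIV,042
17,AIDSHIV,043
17,AIDSHIV,044
18,Lymphoma,200
18,Lymphoma,201
18,Lymphoma,202
18,Lymphoma,2030
18,Lymphoma,2386
19,MetastaticCancer,196
19,MetastaticCancer,197
19,MetastaticCancer,198
19,MetastaticCancer,199
20,SolidTumor,140
20,SolidTumor,141
20,SolidTumor,142
20,SolidTumor,143
20,SolidTumor,144
20,SolidTumor,145
20,SolidTumor,146
20,SolidTumor,147
20,SolidTumor,148
20,SolidTumor,149
20,SolidTumor,150
20,SolidTumor,151
20,SolidTumor,152
20,SolidTumor,153
20,SolidTumor,154
20,SolidTumor,155
20,SolidTumor,156
20,SolidTumor,157
20,SolidTumor,158
20,SolidTumor,159
20,SolidTumor,160
20,SolidTumor,161
20,SolidTumor,162
20,SolidTumor,163
20,SolidTumor,164
20,SolidTumor,165
20,SolidTumor,166
20,SolidTumor,167
20,SolidTumor,168
20,SolidTumor,169
20,SolidTumor,170
20,SolidTumor,171
20,SolidTumor,172
20,SolidTumor,174
20,SolidTumor,175
20,SolidTumor,176
20,SolidTumor,177
20,SolidTumor,178
20,SolidTumor,179
20,SolidTumor,180
20,SolidTumor,181
20,SolidTumor,182
20,SolidTumor,183
20,SolidTumor,184
20,SolidTumor,185
20,SolidTumor,186
20,SolidTumor,187
20,SolidTumor,188
20,SolidTumor,189
20,SolidTumor,190
20,SolidTumor,191
20,SolidTumor,192
20,SolidTumor,193
20,SolidTumor,194
20,SolidTumor,195
21,RheumatoidArthritis,446
21,RheumatoidArthritis,7010
21,RheumatoidArthritis,7100
21,RheumatoidArthritis,7101
21,RheumatoidArthritis,7102
21,RheumatoidArthritis,7103
21,RheumatoidArthritis,7104
21,RheumatoidArthritis,7108
21,RheumatoidArthritis,7109
21,RheumatoidArthritis,7112
21,RheumatoidArthritis,714
21,RheumatoidArthritis,7193
21,RheumatoidArthritis,720
21,RheumatoidArthritis,725
21,RheumatoidArthritis,7285
21,RheumatoidArthritis,72889
21,RheumatoidArthritis,72930
22,Coagulopathy,286
22,Coagulopathy,2871
22,Coagulopathy,2873
22,Coagulopathy,2874
22,Coagulopathy,2875
23,Obesity,2780
24,WeightLoss,260
24,WeightLoss,261
24,WeightLoss,262
24,WeightLoss,263
24,WeightLoss,7832
24,WeightLoss,7994
25,FluidElectrolyte,2536
25,FluidElectrolyte,276
26,BloodLossAnemia,2800
27,DeficiencyAnemia,2801
27,DeficiencyAnemia,2802
27,DeficiencyAnemia,2803
27,DeficiencyAnemia,2804
27,DeficiencyAnemia,2805
27,DeficiencyAnemia,2806
27,DeficiencyAnemia,2807
27,DeficiencyAnemia,2808
27,DeficiencyAnemia,2809
27,DeficiencyAnemia,281
28,AlcoholAbuse,2652
28,AlcoholAbuse,2911
28,AlcoholAbuse,2912
28,AlcoholAbuse,2913
28,AlcoholAbuse,2915
28,AlcoholAbuse,2916
28,AlcoholAbuse,2917
28,AlcoholAbuse,2918
28,AlcoholAbuse,2919
28,AlcoholAbuse,3030
28,AlcoholAbuse,3039
28,AlcoholAbuse,3050
28,AlcoholAbuse,3575
28,AlcoholAbuse,4255
28,AlcoholAbuse,5353
28,AlcoholAbuse,5710
28,AlcoholAbuse,5711
28,AlcoholAbuse,5712
28,AlcoholAbuse,5713
28,AlcoholAbuse,980
28,AlcoholAbuse,V113
29,DrugAbuse,292
29,DrugAbuse,304
29,DrugAbuse,3052
29,DrugAbuse,3053
29,DrugAbuse,3054
29,DrugAbuse,3055
29,DrugAbuse,3056
29,DrugAbuse,3057
29,DrugAbuse,3058
29,DrugAbuse,3059
29,DrugAbuse,V6542
30,Psychoses,2938
30,Psychoses,295
30,Psychoses,29604
30,Psychoses,29614
30,Psychoses,29644
30,Psychoses,29654
30,Psychoses,297
30,Psychoses,298
31,Depression,2962
31,Depression,2963
31,Depression,2965
31,Depression,3004
31,Depression,309
31,Depression,311
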