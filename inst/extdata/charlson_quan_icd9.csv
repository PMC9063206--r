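category,weight,icd9_prefix
MyocardialInfarction,1,410
MyocardialInfarction,1,412
CongestiveHeartFailure,1,39891
CongestiveHeartFailure,1,40201
CongestiveHeartFailure,1,40211
CongestiveHeartFailure,1,40291
CongestiveHeartFailure,1,40401
CongestiveHeartFailure,1,40403
CongestiveHeartFailure,1,40411
CongestiveHeartFailure,1,40413
CongestiveHeartFailure,1,40491
CongestiveHeartFailure,1,40493
CongestiveHeartFailure,1,4254
CongestiveHeartFailure,1,4255
CongestiveHeartFailure,1,4256
CongestiveHeartFailure,1,4257
CongestiveHeartFailure,1,4258
CongestiveHeartFailure,1,4259
CongestiveHeartFailure,1,428
PeripheralVascular,1,0930
PeripheralVascular,1,4373
PeripheralVascular,1,440
PeripheralVascular,1,441
PeripheralVascular,1,4431
PeripheralVascular,1,4432
PeripheralVascular,1,4433
PeripheralVascular,1,4434
PeripheralVascular,1,4435
PeripheralVascular,1,4436
PeripheralVascular,1,4437
PeripheralVascular,1,4438
PeripheralVascular,1,4439
PeripheralVascular,1,4471
PeripheralVascular,1,5571
PeripheralVascular,1,5579
PeripheralVascular,1,V434
Cerebrovascular,1,36234
Cerebrovascular,1,430
Cerebrovascular,1,431
Cerebrovascular,1,432
Cerebrovascular,1,433
Cerebrovascular,1,434
Cerebrovascular,1,435
Cerebrovascular,1,436
Cerebrovascular,1,437
Cerebrovascular,1,438
Dementia,1,290
Dementia,1,2941
Dementia,1,3312
ChronicPulmonary,1,4168
ChronicPulmonary,1,4169
ChronicPulmonary,1,490
ChronicPulmonary,1,491
ChronicPulmonary,1,492
ChronicPulmonary,1,493
ChronicPulmonary,1,494
ChronicPulmonary,1,495
ChronicPulmonary,1,496
ChronicPulmonary,1,500
ChronicPulmonary,1,501
ChronicPulmonary,1,502
ChronicPulmonary,1,503
ChronicPulmonary,1,504
ChronicPulmonary,1,505
ChronicPulmonary,1,5064
ChronicPulmonary,1,5081
ChronicPulmonary,1,5088
Rheumatic,1,4465
Rheumatic,1,7100
Rheumatic,1,7101
Rheumatic,1,7102
Rheumatic,1,7103
Rheumatic,1,7104
Rheumatic,1,7140
Rheumatic,1,7141
Rheumatic,1,7142
Rheumatic,1,7148
Rheumatic,1,725
PepticUlcer,1,531
PepticUlcer,1,532
PepticUlcer,1,533
PepticUlcer,1,534
MildLiver,1,07022
MildLiver,1,07023
MildLiver,1,07032
MildLiver,1,07033
MildLiver,1,07044
MildLiver,1,07054
MildLiver,1,0706
MildLiver,1,0709
MildLiver,1,570
MildLiver,1,5710
MildLiver,1,5712
MildLiver,1,5713
MildLiver,1,5714
MildLiver,1,5715
MildLiver,1,5716
MildLiver,1,5718
MildLiver,1,5719
MildLiver,1,5733
MildLiver,1,5734
MildLiver,1,5738
MildLiver,1,5739
MildLiver,1,V427
DiabetesNoComplication,1,2500
DiabetesNoComplication,1,2501
DiabetesNoComplication,1,2502
DiabetesNoComplication,1,2503
DiabetesNoComplication,1,2508
DiabetesNoComplication,1,2509
DiabetesComplication,2,2504
DiabetesComplication,2,2505
DiabetesComplication,2,2506
DiabetesComplication,2,2507
Hemiplegia,2,3341
Hemiplegia,2,342
Hemiplegia,2,343
Hemiplegia,2,3440
Hemiplegia,2,3441
Hemiplegia,2,3442
Hemiplegia,2,3443
Hemiplegia,2,3444
Hemiplegia,2,3445
Hemiplegia,2,3446
Hemiplegia,2,3449
Renal,2,40301
Renal,2,40311
Renal,2,40391
Renal,2,40402
Renal,2,40403
Renal,2,40412
Renal,2,40413
Renal,2,40492
Renal,2,40493
Renal,2,582
Renal,2,5830
Renal,2,5831
Renal,2,5832
Renal,2,5834
Renal,2,5836
Renal,2,5837
Renal,2,585
Renal,2,586
Renal,2,5880
Renal,2,V420
Renal,2,V451
Renal,2,V56
Malignancy,2,140
Malignancy,2,141
Malignancy,2,142
Malignancy,2,143
Malignancy,2,144
Malignancy,2,145
Malignancy,2,146
Malignancy,2,147
Malignancy,2,148
Malignancy,2,149
Malignancy,2,150
Malignancy,2,151
Malignancy,2,152
Malignancy,2,153
Malignancy,2,154
Malignancy,2,155
Malignancy,2,156
Malignancy,2,157
Malignancy,2,158
Malignancy,2,159
Malignancy,2,160
Malignancy,2,161
Malignancy,2,162
Malignancy,2,163
Malignancy,2,164
Malignancy,2,165
Malignancy,2,166
Malignancy,2,167
Malignancy,2,168
Malignancy,2,169
Malignancy,2,170
Malignancy,2,171
Malignancy,2,172
Malignancy,2,174
Malignancy,2,175
Malignancy,2,176
Malignancy,2,177
Malignancy,2,178
Malignancy,2,179
Malignancy,2,180
Malignancy,2,181
Malignancy,2,182
Malignancy,2,183
Malignancy,2,184
Malignancy,2,185
Malignancy,2,186
Malignancy,2,187
Malignancy,2,188
Malignancy,2,189
Malignancy,2,190
Malignancy,2,191
Malignancy,2,192
Malignancy,2,193
Malignancy,2,194
Malignancy,2,195
Malignancy,2,200
Malignancy,2,201
Malignancy,2,202
Malignancy,2,203
Malignancy,2,204
Malignancy,2,205
Malignancy,2,206
Malignancy,2,207
Malignancy,2,208
Malignancy,2,2386
ModerateSevereLiver,3,4560
ModerateSevereLiver,3,4561
ModerateSevereLiver,3,4562
ModerateSevereLiver,3,5722
ModerateSevereLiver,3,5723
ModerateSevereLiver,3,5724
ModerateSevereLiver,3,5728
MetastaticTumor,6,196
MetastaticTumor,6,197
MetastaticTumor,6,198
MetastaticTumor,6,199
AIDSHIV,6,042
AIDSHIV,6,043
AIDSHIV,6,044
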