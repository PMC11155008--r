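characteristic,row_label,A,B,C,D
response,R,51,31,17,11
response,nR,51,11,15,58
gender,Male,82,34,23,36
gender,Female,20,8,9,33
histological_type,LUAD,48,17,14,40
histological_type,LUSC,54,25,18,29
tumor_stage,T1,10,11,3,8
tumor_stage,T2,32,16,10,21
tumor_stage,T3,34,7,11,16
tumor_stage,T4,26,8,8,24
node_stage,N0,16,10,7,20
node_stage,N1,9,5,6,7
node_stage,N2,51,13,13,19
node_stage,N3,26,14,6,23
metastasis,M0,66,24,22,32
metastasis,M1,36,18,10,37
clinical_stage,IIIA,26,7,12,12
clinical_stage,IIIB,36,14,14,26
clinical_stage,IIIC,7,3,2,4
clinical_stage,IV,33,18,4,27
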