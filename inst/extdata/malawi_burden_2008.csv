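rank,stratum,disease,pct_total
1,persons,HIV/AIDS,28.9
2,persons,Lower respiratory infections,12.0
3,persons,Malaria,8.6
4,persons,Diarrhoeal diseases,8.4
5,persons,Conditions arising during the perinatal period,4.2
6,persons,Tuberculosis,2.2
7,persons,Protein-energy malnutrition,1.9
8,persons,Road traffic accidents,1.6
9,persons,Cataracts,1.1
10,persons,Unipolar depressive disorders,1.0
11,persons,Cerebrovascular disease,0.8
12,persons,Drownings,0.7
13,persons,Ischaemic heart disease,0.7
14,persons,Abortion,0.6
15,persons,Iron-deficiency anaemia,0.5
16,persons,Iodine deficiency,0.5
17,persons,Congenital anomalies,0.5
18,persons,Asthma,0.5
19,persons,Lymphatic filariasis,0.5
20,persons,Violence,0.5
1,males,HIV/AIDS,24.9
2,males,Lower respiratory infections,13.1
3,males,Malaria,8.9
4,males,Diarrhoeal diseases,8.8
5,males,Conditions arising during the perinatal period,5.9
6,males,Tuberculosis,2.9
7,males,Road traffic accidents,2.2
8,males,Protein-energy malnutrition,2.0
9,males,Drownings,1.2
10,males,Cataracts,1.0
11,males,Violence,0.8
12,males,Lymphatic filariasis,0.8
13,males,Ischaemic heart disease,0.8
14,males,Unipolar depressive disorders,0.8
15,males,Cerebrovascular disease,0.7
16,males,Drug use disorders,0.6
17,males,Congenital anomalies,0.6
18,males,Fires,0.6
19,males,Iodine deficiency,0.6
20,males,Asthma,0.6
1,females,HIV/AIDS,32.7
2,females,Lower respiratory infections,10.9
3,females,Malaria,8.4
4,females,Diarrhoeal diseases,8.0
5,females,Conditions arising during the perinatal period,2.6
6,females,Protein-energy malnutrition,1.8
7,females,Tuberculosis,1.5
8,females,Cataracts,1.3
9,females,Unipolar depressive disorders,1.2
10,females,Abortion,1.1
11,females,Road traffic accidents,1.0
12,females,Maternal sepsis,1.0
13,females,Cerebrovascular disease,0.9
14,females,Maternal haemorrhage,0.8
15,females,Trachoma,0.7
16,females,Ischaemic heart disease,0.6
17,females,Iron-deficiency anaemia,0.6
18,females,Iodine deficiency,0.5
19,females,Asthma,0.5
20,females,Congenital anomalies,0.5
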