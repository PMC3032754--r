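intervention,incidence,need_a,provision_b,ratio
Full immunization,,58.5,41.9,0.72
Measles,,45.1,39.4,0.87
ARI in under-5s,1829077,140,68.1,0.49
Malaria - bednets,1200000,91.8,91.8,1.00
Malaria - under 5,2238248,171.3,195.7,1.14
Malaria - 5 and over,1932413,147.9,208.2,1.41
Antenatal Care,797313,61,45.7,0.75
Normal Delivery,637850,43.9,22.7,0.52
Delivery complications,115786,10.4,3.2,0.31
Newborn Complications,127570,9.8,0.8,0.08
Abortion Complications,55481,4.2,1.4,0.33
Treatment of Syphilis in Pregnancy,31095,2.4,2.2,0.92
Postpartum Care,637850,48.8,13,0.27
Condoms,12301,6.5,5,0.77
Oral Contraceptive Pill,10854,7.8,6,0.77
Depo-provera injection,100582,9.4,7.2,0.77
Norplant,2894,0.1,0.1,1.00
IUCD,724,0.1,0.1,1.00
Bilateral Tubular Ligation,,2.9,2.1,0.72
Vasectomy,,0.1,0.1,1.00
Passive Case Detection,,6.2,4.4,0.71
Treatment -smear negative and extra-pulmonary TB,,3.6,2.6,0.72
Treatment -smear positive TB,,0.9,0.6,0.67
Treatment - relapsed cases,,0.2,0.2,1.00
Treatment of Dehydration in U5s,3815318,292,25.5,0.09
Case management in Cholera,,0.1,0.1,1.00
Case management of Dysentery,,14.2,8.5,0.60
HIV Testing & Counselling (HTC),1191648,91.2,54.7,0.60
Management of OIs,261325,20,12,0.60
Screening/treatment of syphilis,148956,11.4,6.8,0.60
Prevention of MTC transmission,78137,12.2,0.6,0.05
Testing and Treatment of Other STIs,436676,33.4,12.8,0.38
CBHBC,37892,2.9,0.8,0.28
ARV (adult),79200,5.6,3.4,0.61
ARV (child),10800,0.8,0.5,0.63
ARV Supplementary Feeding (adult),79200,1,0.6,0.60
ARV Supplementary Feeding (child),10800,0.9,0.5,0.56
Diagnosis and Case Management,4401521,11.5,6.9,0.60
Mass Treatment,352647,27,16.2,0.60
Growth Monitoring of U5 Children,2383085,182.4,183.2,1.00
Micronutrient supplementation,2383085,182.4,109.4,0.60
Severe Acute Malnutrition (Inpatient),44162,3.4,1.4,0.41
Moderate Acute Malnutrition (Outpatient),40375,3.1,2.5,0.81
Supplementary Feeding,244732,18.7,7.7,0.41
Treatment of conjunctivitis,,45.6,27.3,0.60
Acute otitis media in under 5s,1089317,7.3,4.4,0.60
Scabies,,62.6,37.6,0.60
Treatment of Fractures and Dislocations,164244,12.6,10.1,0.80
Treatment of Wounds,213765,16.4,15.3,0.93
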