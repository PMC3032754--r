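intervention,denominator_class,y2002_03,y2003_04,y2004_05,y2005_06,y2006_07,y2007_08
Antenatal total visits,live_births,3057,1920,2694,2475,2320,2486
Delivery by skilled personnel,live_births,422,266,453,416,422,493
Woman with obstetric complication treated at obstetric care facility,live_births,46,28,30,31,33,39
Caesarean section,live_births,19,11,20,23,22,26
Abortion complications treated,live_births,,,16,17,21,23
Woman of reproductive age receiving modern family planning methods,female15to45,651,435,221,159,137,160
BCG,live_births,633,561,936,951,957,1042
Pentavalent III,live_births,569,465,695,796,808,910
Polio-III,live_births,570,464,800,786,803,920
Measles 1st dose at 9 months,live_births,492,368,658,691,728,857
Vitamin A dose to 6 - 59 months population,under5,323,0,373,372,346,579
Volunteer counselling confidential test and serostatus result 15-49 y,adult15plus,12,0,26,43,66,103
HIV test positive 15-49 years,adult15plus,,,6,10,13,20
HIV positive person receiving anti-retroviral treatment,adult15plus,,,2,9,21,18
Pregnant woman receiving VCT and serostatus result,female15to45,,,5,17,31,48
Pregnant woman tested HIV positive,live_births,,,9,25,43,60
Nevirapine dose to baby born to woman with HIV,live_births,,,1,2,2,4
Home-based Care patient followed-up and provided treatment,adult15plus,,,8,13,17,23
Case treated as STI - new,adult15plus,,,29,27,24,23
Child attending under-five clinic,under5,2081,1321,2116,2193,2239,2571
Acute Respiratory Infections under 5 years - new,under5,,,265,337,338,348
Diarrhoea non-bloody under 5 years - new,under5,108,64,122,148,119,130
Malnutrition under 5 years - new,under5,65,28,34,48,41,32
Malaria under 5 years - new,under5,,,657,849,831,999
Malaria 5 years and older - new,over5,,,194,215,220,251
Dysentery - new,total,6,4,7,7,8,8
Eye infection - new,total,,,26,32,23,27
Ear infection - new,total,,6,10,12,10,10
Skin infection - new,total,,,32,40,34,37
Oral condition - new,total,,,25,29,27,29
Schistosomiasis - new,total,,,5,6,8,7
Leprosy - new,total,,,0,0,0,0
Common injuries and wounds,total,,,20,26,26,25
OPD total attendance,total,929,520,815,1058,911,1135
Admissions,total,35,19,49,53,55,58
Inpatient days,total,124,81,132,147,160,179
Inpatient discharges,total,,,39,46,49,56
Inpatient deaths (excluding maternity),total,47,65,38,34,28,30
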