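intervention,usd_per_daly_low,usd_per_daly_high,in_ehp,targets_top20,externally_funded,source
DTP and measles vaccines,7,7,TRUE,TRUE,FALSE,DCP2
Pentavaccine,298,298,TRUE,TRUE,FALSE,DCP2
Commercial ORS for dehydration,1060,1060,TRUE,TRUE,FALSE,DCP2
Home made ORS,4,4,FALSE,TRUE,FALSE,DCP2
Antiretroviral therapy,922,922,TRUE,TRUE,TRUE,DCP2
Supplementary feeding for children,225,225,TRUE,TRUE,FALSE,DCP2
IPPT of malaria in children,3,12,FALSE,TRUE,FALSE,DCP2
Treatment of LRI through child clinics,129,129,TRUE,TRUE,FALSE,DCP2
IMCI,39,39,FALSE,TRUE,FALSE,DCP2
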