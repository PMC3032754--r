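fiscal_year,expenditure_pc,required_pc,scope
2002/03,7.9,17.3,swap_ehp
2007/08,13.5,28.6,swap_ehp
2005/06,25,34,national_total
2015/16,,38,national_total
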