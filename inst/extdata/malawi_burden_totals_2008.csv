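stratum,dalys,pct_printed
total,7500000,100
under15,2100000,29
adults,5400000,72
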