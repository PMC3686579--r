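name	sequence	orientation	three_prime_block
LCO1490	GGTCAACAAATCATAAAGATATTGG	forward	FALSE
HCO2198	TAAACTTCAGGGTGACCAAAAAATCA	reverse	FALSE
dgLCO1490	GGTCAACAAATCATAAAGAYATYGG	forward	FALSE
dgHCO2198	TAAACTTCAGGGTGACCAAARAAYCA	reverse	FALSE
jgLCO1490	TITCIACIAAYCAYAARGAYATTGG	forward	FALSE
jgHCO2198	TAIACYTCIGGRTGICCRAARAAYCA	reverse	FALSE
Uni-MinibarF1	CAAAATCATAATGAAGGCATGAGC	forward	FALSE
Uni-MinibarR1	TCCACTAATCACAARGATATTGGTAC	reverse	FALSE
mlCOIintF	GGWACWGGWTGAACWGTWTAYCCYCC	forward	FALSE
mlCOIintR	GGRGGRTASACSGTTCASCCSGTSCC	reverse	FALSE
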