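# Machine-readable list of known inconsistencies carried as-printed in the
# packaged tables. Nothing is corrected in the transcriptions themselves.
table	row	issue	detail	suggested_composition
cortex	23	mass-inconsistent	printed m/z 1905.58 with composition (Hex)8(HexNAc)2 duplicates row 21 and matches (Hex)9(HexNAc)2 [M+Na]+ (theoretical 1905.63), not the printed composition (theoretical 1743.58)	(Hex)9(HexNAc)2
cortex	43	mass-inconsistent	printed m/z 1979.33 deviates ~1.6 Da from the theoretical [M-2H+Na]- value 1977.69 of the printed composition	NA
serum	46	narrative-count	detectable in the model group and undetectable after treatment, so it meets the suppression rule, but the narrative inhibited list omits it (rule-derived modulated count 7 vs narrative 6)	NA
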