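accession	expected_total
AC256511.1	588
AC257258.1	984
AC259365.1	666
AC261250.1	529
AC263353.1	167
AC264961.1	728
AC265197.1	549
AC266636.1	861
AC267178.1	540
AC269605.1	762
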