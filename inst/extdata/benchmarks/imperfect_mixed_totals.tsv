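sequence	accession	expected_total
Yeast_Chr4	NC_001136.8	40239
Plasmodium_Chr4	NC_004318.1	55693
MTB_H37Rv	NC_000962.2	111583
Human_Atrophin1	BC051795	146
Ecoli_K12	NC_000913.2	106243
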