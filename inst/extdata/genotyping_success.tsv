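# One-time genotyping success of the 13-SNP panel.
# Sample sizes: wolf n = 97, dog n = 108, overall n = 205.
# The printed per-table average row (0.990 / 0.993 / 0.991) covers the 12
# loci retained after discarding rs22103787 and is recomputed, not stored.
locus_id	wolf	dog	overall
rs22103787	0.926	0.444	0.673
rs22835438	1.000	0.991	0.995
rs23249721	1.000	1.000	1.000
rs23608542	0.969	0.991	0.980
rs23882488	1.000	0.991	0.995
rs24163825	0.990	1.000	0.995
rs24189603	1.000	0.972	0.985
rs24198287	1.000	1.000	1.000
rs24355642	0.938	1.000	0.971
rs24383001	0.979	1.000	0.990
rs24863098	1.000	1.000	1.000
rs9089629	1.000	0.991	0.995
rs9159232	1.000	0.981	0.990
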