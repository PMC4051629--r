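saltans_table2.csv

Discrete character matrix of 19 male terminalia and aedeagus structures
scored across ten species of the Drosophila saltans species group
(subgroups: saltans - prosaltans, lusaltans, saltans, austrosaltans;
sturtevanti - sturtevanti, dacunhai, milleri; parasaltans - parasaltans;
cordata - neocordata; elliptica - emarginata) plus the outgroup
D. willistoni, whose row is all zeros.

State legend: 0 = structure absent, 1 = present, 2 = present with
modifications (characters 5 and 13 only).  No missing data.

Format: CSV, header row flagged by the "#taxon" sentinel, first field the
taxon label, then one state per character in the canonical 1-19 order.
Character descriptions are attached by mpsaltans::saltans_matrix().
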