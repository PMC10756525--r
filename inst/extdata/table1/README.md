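# Pooled circulating-miRNA signature fixture

Four per-study signature files (`study1.tsv` .. `study4.tsv`, tab-separated,
columns `mirna_id` and `direction`) transcribing the pooled published
signature of 56 circulating miRNAs differentially expressed in ME/CFS
versus healthy controls: 37 elevated (`high`), 19 decreased (`low`), and 4
miRNAs (hsa-miR-21-5p, hsa-miR-126-3p, hsa-miR-127-3p, hsa-miR-150-5p)
independently reported by two studies.

The published table reports only the pooled lists and the two-study
multiplicity flags, not per-study membership. The split of the remaining 52
single-study miRNAs across the four files is therefore a SYNTHETIC
partition (round-robin), consistent with the multiplicity flags: the four
dual-study miRNAs appear in exactly two files each, all others in exactly
one. Aggregated counts (56 / 37 / 19 / 4) are exact; individual study
attribution is not meaningful.

Loaded via `parseTable1Fixture()`, which verifies md5 checksums.
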