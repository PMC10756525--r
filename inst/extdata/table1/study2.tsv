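mirna_id	direction
hsa-let-7g-5p	high
hsa-miR-126-3p	high
hsa-miR-127-3p	high
hsa-miR-140-5p	high
hsa-miR-185-5p	high
hsa-miR-21-5p	high
hsa-miR-331-3p	high
hsa-miR-381-3p	high
hsa-miR-548j-5p	high
hsa-miR-6076	high
hsa-miR-92a-3p	high
hsa-let-7g-3p	low
hsa-miR-126-5p	low
hsa-miR-3065-3p	low
hsa-miR-450b-5p	low
hsa-miR-6507-3p	low
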