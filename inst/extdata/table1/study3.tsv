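mirna_id	direction
hsa-miR-127-3p	high
hsa-miR-142-5p	high
hsa-miR-150-5p	high
hsa-miR-15a-5p	high
hsa-miR-200c-3p	high
hsa-miR-370-3p	high
hsa-miR-423-5p	high
hsa-miR-4454	high
hsa-miR-6717-5p	high
hsa-miR-93-5p	high
hsa-miR-16-2-3p	low
hsa-miR-183-5p	low
hsa-miR-3620-3p	low
hsa-miR-486-5p	low
hsa-miR-6800-3p	low
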