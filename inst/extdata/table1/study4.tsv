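mirna_id	direction
hsa-miR-130a-3p	high
hsa-miR-143-3p	high
hsa-miR-150-5p	high
hsa-miR-223-3p	high
hsa-miR-29a-3p	high
hsa-miR-374a-5p	high
hsa-miR-4532	high
hsa-miR-493-5p	high
hsa-miR-6875-5p	high
hsa-miR-203a-5p	low
hsa-miR-26a-1-3p	low
hsa-miR-4433a-5p	low
hsa-miR-607	low
hsa-miR-6819-3p	low
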