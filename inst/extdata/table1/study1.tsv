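mirna_id	direction
hsa-let-7d-5p	high
hsa-miR-126-3p	high
hsa-miR-136-3p	high
hsa-miR-181b-5p	high
hsa-miR-21-5p	high
hsa-miR-320e	high
hsa-miR-34a-5p	high
hsa-miR-374b-5p	high
hsa-miR-548ax	high
hsa-miR-5581-5p	high
hsa-miR-7975	high
hsa-miR-33a-5p	low
hsa-miR-369-3p	low
hsa-miR-5187-3p	low
hsa-miR-641	low
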