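# Published per-category lifestyle counts for a 21,499-vOTU human gut
# virome catalogue (DeePhage score bins 0.3 / 0.5 / 0.7).
category	count
temperate	3419
uncertain_temperate	11869
uncertain_virulent	4733
virulent	1548
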