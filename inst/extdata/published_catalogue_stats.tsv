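# Headline size of the published human gut virome catalogue.
stat	value
n_votus	21499
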