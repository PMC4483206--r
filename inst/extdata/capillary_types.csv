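# Capillary wall type per organ. Sinusoidal walls are the most permeable,
# continuous (non-fenestrated) the least. User-replaceable.
organ,capillary_type
lung,continuous
liver,sinusoidal
spleen,sinusoidal
kidneys,fenestrated
heart,continuous
brain,continuous
GIT_tissue,fenestrated
remainder,continuous
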