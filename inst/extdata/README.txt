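Synthetic placeholder signature files (GMT, directional *_UP/*_DN dialect).

senescence_synthetic.gmt  33 up / 67 down placeholder symbols matching the
                          cardinality of a directional senescence signature;
                          NOT the authoritative gene list, which users must
                          supply from the signature's published supplement.
exhaustion_synthetic.gmt  canonical T-cell exhaustion markers, up-only.
anergy_synthetic.gmt      canonical T-cell anergy markers, up-only.

These files exist so the loaders and the pipeline can be exercised without
external downloads; real analyses should pass their own curated signature
files to load_signature().
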