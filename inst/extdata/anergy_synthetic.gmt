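ANERGY_SYNTHETIC_UP	synthetic placeholder	EGR2	EGR3	NR4A1	NR4A2	NR4A3	IZUMO1R	TLE4	RNF128
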