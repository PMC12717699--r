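EXHAUSTION_SYNTHETIC_UP	synthetic placeholder	PDCD1	CTLA4	LAG3	HAVCR2	TIGIT	TOX	ENTPD1	CD160	BTLA	EOMES
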