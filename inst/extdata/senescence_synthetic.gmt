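SENESCENCE_SYNTHETIC_UP	synthetic placeholder	SENUP001	SENUP002	SENUP003	SENUP004	SENUP005	SENUP006	SENUP007	SENUP008	SENUP009	SENUP010	SENUP011	SENUP012	SENUP013	SENUP014	SENUP015	SENUP016	SENUP017	SENUP018	SENUP019	SENUP020	SENUP021	SENUP022	SENUP023	SENUP024	SENUP025	SENUP026	SENUP027	SENUP028	SENUP029	SENUP030	SENUP031	SENUP032	SENUP033
SENESCENCE_SYNTHETIC_DN	synthetic placeholder	SENDN001	SENDN002	SENDN003	SENDN004	SENDN005	SENDN006	SENDN007	SENDN008	SENDN009	SENDN010	SENDN011	SENDN012	SENDN013	SENDN014	SENDN015	SENDN016	SENDN017	SENDN018	SENDN019	SENDN020	SENDN021	SENDN022	SENDN023	SENDN024	SENDN025	SENDN026	SENDN027	SENDN028	SENDN029	SENDN030	SENDN031	SENDN032	SENDN033	SENDN034	SENDN035	SENDN036	SENDN037	SENDN038	SENDN039	SENDN040	SENDN041	SENDN042	SENDN043	SENDN044	SENDN045	SENDN046	SENDN047	SENDN048	SENDN049	SENDN050	SENDN051	SENDN052	SENDN053	SENDN054	SENDN055	SENDN056	SENDN057	SENDN058	SENDN059	SENDN060	SENDN061	SENDN062	SENDN063	SENDN064	SENDN065	SENDN066	SENDN067
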