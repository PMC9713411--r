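sample_id	group	phase
S001	RRMS	relapse
S002	RRMS	remission
S003	RRMS	relapse
S004	RRMS	remission
S005	RRMS	relapse
S006	RRMS	remission
S007	NINDC	none
S008	INDC	none
S009	NINDC	none
S010	INDC	none
S011	NINDC	none
S012	INDC	none
S013	SPMS	progressive
S014	SPMS	progressive
S015	SPMS	progressive
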