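lineage	gene_id	isoform	paralog_group
Chromerida	vbra_nth_ab	ALPHA_BETA	NA
Chromerida	vbra_nth_ba1	BETA_ALPHA	GROUP_I
Chromerida	cvel_nth_ba2	BETA_ALPHA	GROUP_II
Gregarinia	poro_nth_ab1	ALPHA_BETA	NA
Gregarinia	poro_nth_ab2	ALPHA_BETA	NA
Gregarinia	poro_nth_ab3	ALPHA_BETA	NA
Gregarinia	poro_nth_ba1	BETA_ALPHA	GROUP_II
Gregarinia	poro_nth_ba2	BETA_ALPHA	GROUP_II
Marosporida	rhyt_nth_ab1	ALPHA_BETA	NA
Marosporida	rhyt_nth_ab2	ALPHA_BETA	NA
Marosporida	rhyt_nth_ba1	BETA_ALPHA	GROUP_II
Marosporida	rhyt_nth_ba2	BETA_ALPHA	GROUP_II
Cryptosporidia	cpar_nth_ba1	BETA_ALPHA	GROUP_I
Cryptosporidia	cpar_nth_ba2	BETA_ALPHA	GROUP_I
Nephromycida	ccio_nth_ba1	BETA_ALPHA	GROUP_II
Nephromycida	ccio_nth_ba2	BETA_ALPHA	GROUP_II
Nephromycida	neph_nth_ba1	BETA_ALPHA	GROUP_II
Nephromycida	neph_nth_ba2	BETA_ALPHA	GROUP_II
Nephromycida	neph_nth_ba3	BETA_ALPHA	GROUP_II
Sarcocystidae	tgon_nth_ba1	BETA_ALPHA	GROUP_I
Sarcocystidae	tgon_nth_ba2	BETA_ALPHA	GROUP_II
Eimeriidae	eten_nth_ba1	BETA_ALPHA	GROUP_I
Haemosporida	pfal_nth_ba1	BETA_ALPHA	GROUP_I
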