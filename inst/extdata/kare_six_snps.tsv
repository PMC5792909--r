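marker	gene	chrom	pos	minor	major	maf	n_major_hom	n_het	n_minor_hom	tc_hdl_major_hom	tc_hdl_het	tc_hdl_minor_hom	logtg_hdl_major_hom	logtg_hdl_het	logtg_hdl_minor_hom	weight_tc_hdl	weight_log_tg_hdl	trend_sign
rs4420638	APOC1	19	44919689	G	A	0.111	6181	1502	112	4.163	4.402	4.485	0.0451	0.0478	0.0488	0.239	0.00249	1
rs6589566	ZPR1	11	116781707	G	A	0.216	4783	2649	363	4.156	4.274	4.527	0.0446	0.0471	0.0504	0.136	0.00274	1
rs12421652	BUD13	11	116755159	T	G	0.203	4959	2515	321	4.282	4.107	4.003	0.0467	0.0442	0.0417	0.139	0.00233	-1
rs17411126	LPL	8	19997761	C	T	0.207	4896	2564	335	4.262	4.151	3.986	0.0466	0.0443	0.0422	0.118	0.00227	-1
rs16940212	LOC101928635	15	58401821	T	G	0.340	3394	3497	904	4.274	4.196	4.056	0.0465	0.0456	0.0433	0.079	0.00095	-1
rs10852765	ABCA8	17	68888738	G	A	0.437	2473	3824	1498	4.170	4.215	4.282	0.0448	0.0460	0.0464	0.051	0.00066	1
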