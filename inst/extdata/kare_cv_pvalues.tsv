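marker	trait	selection_set	set1	set2	set3	set4	set5	set6	set7	set8	set9	set10
rs4420638	tc_hdl	4.49e-14	6.64e-13	6.87e-13	1.81e-11	6.87e-13	2.70e-13	2.12e-12	1.09e-13	6.41e-13	8.74e-13	5.85e-13
rs4420638	log_tg_hdl	3.75e-11	1.65e-10	9.19e-10	1.54e-9	9.19e-10	1.21e-10	2.21e-9	1.16e-10	5.33e-11	2.49e-10	1.57e-10
rs6589566	tc_hdl	2.99e-8	2.05e-7	6.07e-8	2.30e-7	6.07e-8	6.83e-8	5.93e-8	4.20e-7	4.98e-7	2.00e-7	8.42e-8
rs6589566	log_tg_hdl	2.73e-21	4.40e-18	4.77e-19	2.46e-19	4.77e-19	1.71e-19	2.30e-19	3.86e-18	1.47e-17	1.99e-18	2.39e-18
rs12421652	tc_hdl	3.42e-8	6.92e-8	3.25e-8	7.19e-8	3.25e-8	8.21e-8	6.71e-8	1.66e-7	2.49e-7	2.79e-7	7.23e-8
rs12421652	log_tg_hdl	5.17e-15	2.09e-13	2.01e-14	2.95e-15	2.01e-14	7.55e-15	3.84e-14	6.34e-14	4.98e-12	2.15e-13	7.50e-13
rs17411126	tc_hdl	1.76e-6	1.02e-6	2.43e-6	1.99e-6	2.43e-6	4.76e-6	7.45e-6	1.04e-5	2.94e-7	6.67e-6	5.16e-6
rs17411126	log_tg_hdl	9.70e-15	3.48e-14	1.98e-12	1.75e-14	1.98e-12	3.59e-13	5.87e-13	8.01e-13	4.74e-15	2.63e-13	9.89e-14
rs16940212	tc_hdl	0.0002	0.001	0.002	0.0002	0.002	0.0006	0.0002	0.001	0.0007	0.0003	0.0002
rs16940212	log_tg_hdl	0.0002	0.0002	0.001	0.0002	0.001	0.00004	0.00003	0.0005	0.0006	0.0002	0.0001
rs10852765	tc_hdl	0.01	0.008	0.005	0.006	0.005	0.007	0.008	0.007	0.01	0.01	0.006
rs10852765	log_tg_hdl	0.006	0.006	0.005	0.007	0.005	0.003	0.007	0.008	0.009	0.005	0.004
rs12229654	tc_hdl	2.71e-5	0.0002	0.0003	9.50e-5	0.0003	0.0001	0.0007	0.0005	0.0002	0.0001	0.0002
rs12229654	log_tg_hdl	0.01	0.02	0.01	0.02	0.01	0.02	0.03	0.03	0.03	0.02	0.03
rs1250252	tc_hdl	0.0006	0.001	0.001	0.001	0.001	0.003	0.001	0.002	0.0004	0.0003	0.0004
rs1250252	log_tg_hdl	0.01	0.009	0.01	0.02	0.01	0.05	0.01	0.04	0.003	0.003	0.002
rs12686004	tc_hdl	0.006	0.008	0.005	0.02	0.005	0.02	0.009	0.04	0.008	0.006	0.003
rs12686004	log_tg_hdl	1.23e-6	5.90e-6	5.63e-6	2.00e-5	5.63e-6	1.68e-5	5.69e-6	2.48e-5	2.03e-6	1.79e-6	6.51e-7
rs164212	tc_hdl	0.009	0.01	0.009	0.006	0.009	0.01	0.008	0.01	0.008	0.01	0.006
rs164212	log_tg_hdl	0.01	0.01	0.004	0.01	0.004	0.006	0.005	0.004	0.05	0.03	0.02
rs2297194	tc_hdl	0.01	0.04	0.03	0.009	0.03	0.02	0.006	0.01	0.07	0.06	0.02
rs2297194	log_tg_hdl	2.34e-5	5.01e-5	4.25e-5	3.30e-6	4.25e-5	3.81e-5	1.77e-5	3.36e-5	0.0002	0.0004	5.76e-5
rs496311	tc_hdl	0.01	0.03	0.08	0.03	0.08	0.03	0.03	0.02	0.03	0.03	0.03
rs496311	log_tg_hdl	0.003	0.004	0.01	0.006	0.01	0.007	0.009	0.004	0.004	0.005	0.008
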