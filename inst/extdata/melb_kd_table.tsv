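protein	ligand	condition_ref	condition_test	kd_ref	kd_ref_sem	n_ref	kd_test	kd_test_sem	n_test	unit	printed_fold
WT	melibiose	no Na+, pH 7.5	100 mM Na+, pH 7.5	9.28	0.23	3	1.09	0.06	4	mM	8.51
WT	aNPG	no Na+, pH 7.5	100 mM Na+, pH 7.5	43.20	0.62	2	25.69	4.42	2	uM	1.68
D55C	melibiose	no Na+, pH 7.5	100 mM Na+, pH 7.5	5.82	0.46	2	5.09	0.15	2	mM	1.14
D55C	aNPG	no Na+, pH 7.5	100 mM Na+, pH 7.5	15.06	1.86	2	13.54	1.38	2	uM	1.11
WT	melibiose	pH 8.5, no Na+	pH 6.25, no Na+	8.50	0.21	3	6.19	0.59	2	mM	1.37
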