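pair001/1	NC_CHK_1.1	99.3	150	1	0	1	150	5000	5149	1e-60	278	150
pair001/2	NC_CHK_1.1	98.7	150	2	0	1	150	5350	5499	1e-58	272	150
pair002/1	NC_CHK_1.1	99.3	150	1	0	1	150	8000	8149	1e-60	278	150
pair002/2	NC_CHK_1.1	100.0	150	0	0	1	150	8499	8350	1e-62	283	150
pair003/1	NC_CHK_1.1	97.3	150	4	0	1	150	12000	12149	1e-55	265	150
pair003/2	NC_CHK_1.1	99.3	150	1	0	1	150	12350	12499	1e-60	278	150
pair004/1	NC_CHK_1.1	99.3	150	1	0	1	150	41000	41149	1e-60	278	150
pair004/2	NC_CHK_1.1	98.0	150	3	0	1	150	41350	41499	1e-57	270	150
pair005/1	NC_CHK_1.1	96.0	150	6	0	1	150	70000	70149	1e-52	258	150
pair005/2	NC_CHK_1.1	99.3	150	1	0	1	150	70355	70504	1e-60	278	150
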