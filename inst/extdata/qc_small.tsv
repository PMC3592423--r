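chip	experiment	scale_factor	biob_present	rle_center	rle_iqr	nuse_center	nuse_iqr
chip01	expA	1.1	TRUE	0.039	0.34	1.022	0.176
chip02	expA	1.1	TRUE	-0.012	0.199	0.966	0.206
chip03	expA	1.1	TRUE	0.018	0.426	0.985	0.108
chip04	expA	1.1	TRUE	0.014	0.217	0.998	0.198
chip05	expA	1.1	TRUE	-0.005	0.218	1.03	0.389
chip06	expA	1.1	TRUE	0.038	0.456	0.965	0.199
chip07	expA	1.1	TRUE	0.007	0.379	0.991	0.341
chip08	expA	1.1	TRUE	0.015	0.192	1.039	0.348
chip09	expA	1.1	TRUE	-0.015	0.116	1.027	0.315
chip10	expA	1.1	TRUE	0.025	0.409	0.984	0.104
chip11	expA	1.1	TRUE	-0.02	0.262	1.009	0.251
chip12	expA	1.1	TRUE	-0.005	0.173	0.968	0.273
chip13	expA	1.1	TRUE	0.026	0.256	1.027	0.117
chip14	expA	1.1	TRUE	0.004	0.467	0.97	0.389
chip15	expA	1.1	TRUE	-0.039	0.37	1.026	0.294
chip16	expB	1.1	TRUE	-0.026	0.194	0.979	0.118
chip17	expB	1.1	TRUE	0.033	0.37	1.003	0.149
chip18	expB	1.1	TRUE	-0.012	0.313	1.038	0.492
chip19	expB	1.1	TRUE	-0.013	0.386	0.964	0.101
chip20	expB	1.1	TRUE	-0.004	0.497	0.985	0.226
chip21	expB	1.1	TRUE	0.034	0.269	1.035	0.462
chip22	expB	1.1	TRUE	-0.035	0.441	1.035	0.182
chip23	expB	1.1	TRUE	-0.026	0.329	0.978	0.101
chip24	expB	1.1	TRUE	0.001	0.376	1.011	0.101
chip25	expB	1.1	TRUE	0.006	0.278	1.037	0.102
chip26	expB	1.1	TRUE	0.046	0.299	0.992	0.447
chip27	expB	1.1	TRUE	-0.023	0.102	1.032	0.334
chip28	expB	1.1	TRUE	0.004	0.293	0.994	0.187
chip29	expB	9	TRUE	0.049	0.447	0.999	0.423
chip30	expB	1	FALSE	-0.019	0.314	0.967	0.133
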