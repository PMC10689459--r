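curve_id	label	sigma	pEC50	slope	front	back	cfc
null_000014	null	0.0341459442507752	NA	NA	1	1	0
null_000015	null	0.0846490320262847	NA	NA	1	1	0
reg_000005	down	0.039857630572111	6.92523655667901	1.18661266437266	1	0.255724157178281	-1.96733964257874
reg_000006	down	0.00589169969923009	6.5572878473904	1.57866837747861	1	0.625798001976405	-0.676231042481959
null_000008	null	0.0820727365453131	NA	NA	1	1	0
reg_000004	down	0.0836724796013995	7.49134287820198	1.55759717605542	1	0.266088527749862	-1.91002178413328
null_000003	null	0.169608437560161	NA	NA	1	1	0
null_000002	null	0.0206574488215518	NA	NA	1	1	0
null_000001	null	0.0245458624339121	NA	NA	1	1	0
null_000004	null	0.061698201298905	NA	NA	1	1	0
null_000006	null	0.0454659439139266	NA	NA	1	1	0
null_000009	null	0.0420727649446595	NA	NA	1	1	0
null_000010	null	0.043254884110578	NA	NA	1	1	0
null_000005	null	0.0538212871982182	NA	NA	1	1	0
null_000018	null	0.0250450898799956	NA	NA	1	1	0
null_000017	null	0.0204749991401041	NA	NA	1	1	0
reg_000001	up	0.016364349812114	7.74441813048907	1.6048824719619	1	3.73733107201527	1.90200837072916
reg_000003	down	0.0450129558213692	5.85841860435903	1.48548843560275	1	0.437259237001511	-1.1934392338153
reg_000002	up	0.0400335341880081	7.81122623989359	0.701999895856716	1	1.84438934505747	0.883143236511387
null_000011	null	0.106333770783418	NA	NA	1	1	0
null_000013	null	0.153900748336529	NA	NA	1	1	0
null_000007	null	0.0191418931069893	NA	NA	1	1	0
null_000016	null	0.153776035347888	NA	NA	1	1	0
null_000012	null	0.0971897776783599	NA	NA	1	1	0
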