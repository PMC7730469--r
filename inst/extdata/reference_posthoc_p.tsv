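signal	feature	p_baseline_min30	padj_baseline_min30	p_baseline_min60	padj_baseline_min60	p_min30_min60	padj_min30_min60
ax	range	0.17	0.51	0.006	0.018	0.17	0.51
ax	median_abs	0.17	0.51	0	0	0.016	0.049
ay	rms	0.016	0.049	1	1	0.026	0.077
ay	variance	0.016	0.049	1	1	0.026	0.077
ay	min_abs	0.303	0.91	0.01	0.03	0	0.001
ay	ec	0.016	0.049	1	1	0.026	0.077
az	skewness	1	1	0.016	0.049	0.026	0.077
az	median_abs	1	1	0.026	0.077	0.016	0.049
wx	rms	1	1	0.01	0.03	0.04	0.119
wx	max_abs	1	1	0.016	0.049	0.026	0.077
wx	ec	1	1	0.006	0.018	0.059	0.178
gx	rms	0.026	0.077	0.016	0.049	1	1
gx	max_abs	0.016	0.049	0	0	0.17	0.51
gx	range	0.016	0.049	0	0	0.17	0.51
gx	ec	0.026	0.077	0.016	0.049	1	1
gy	rms	0.23	0.69	0.004	0.011	0.086	0.259
gy	ec	0.23	0.69	0.004	0.011	0.086	0.259
gz	kurtosis	0.23	0.69	0.004	0.011	0.086	0.259
gz	skewness	0.303	0.91	0.01	0.03	0.123	0.368
gz	rms	0.002	0.006	0.002	0.006	1	1
gz	max_abs	0.004	0.011	0.001	0.003	1	1
gz	min_abs	0.006	0.018	0.004	0.011	1	1
gz	range	0.004	0.011	0.006	0.018	1	1
gz	median_abs	0.004	0.011	0.006	0.018	1	1
gz	ec	0	0.001	0	0.001	1	1
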