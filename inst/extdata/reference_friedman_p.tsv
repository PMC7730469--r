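feature	ax	ay	az	wx	wy	wz	gx	gy	gz
mad	0.113	0.056	0.494	0.327	0.662	0.390	0.327	0.943	0.662
kurtosis	0.838	0.120	0.113	0.838	0.113	0.193	0.113	0.230	0.014
skewness	0.790	0.494	0.028	0.080	0.589	0.662	0.465	0.161	0.035
rms	0.080	0.028	0.390	0.025	0.589	0.327	0.028	0.014	0.002
variance	0.204	0.028	0.662	0.056	0.790	0.193	0.113	0.943	0.943
max_abs	0.056	0.465	0.193	0.028	0.790	0.080	0.001	0.080	0.002
min_abs	0.465	0.001	0.193	0.494	0.113	0.790	0.494	0.790	0.005
range	0.023	0.465	0.193	0.059	0.790	0.193	0.001	0.080	0.005
median_abs	0.001	0.494	0.028	0.589	0.790	0.390	0.662	0.327	0.005
ec	0.193	0.028	0.230	0.019	0.790	0.291	0.028	0.014	0.000
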