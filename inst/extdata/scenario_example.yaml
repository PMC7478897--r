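# Example synthetic-cohort scenario: moderate continued breastfeeding,
# slowly diversifying complementary diet.
n_clusters: 60
children_per_cluster: 15
n_strata: 4
weight_dispersion: 0.25
bf_logit_intercept: 3.0
bf_logit_slope: -0.13
group_logit_intercepts: [-0.5, -2.2, -2.0, -2.1, -3.0, -1.7, -2.0]
group_logit_slope: 0.08
child_heterogeneity_sd: 0.9
label: example
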