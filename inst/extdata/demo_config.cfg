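# Demonstration run configuration for run_pipeline()
# (flat key: value dialect parsed by read_run_config)
n_individuals: 500
theta: -0.4, 0
seed: 42
min_rt: 35
min_dup_corr: 0.5
outlier_sd: 3
fdr_q: 0.05
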