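# Example experiment config for `run_experiment()` / the ideapop.R CLI:
# backward-master-equation fixation-time heat map of the Matching Pennies
# chain. Override any registered default; unknown keys are rejected.
experiment: mp_heatmap
N: 30
lam: 0.3
seed: 1
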