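# Shared configuration for the numbered analysis drivers.
seed: 42
n_prescriptions: 20000
min_support: 1.0
min_confidence: 15.0
min_lift: 1.0
top_n: 100
cluster_method: greedy
ob_min: 0.30
dl_min: 0.18
ob_units: fraction
alpha: 0.05
correction: BH
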