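# Default synthetic registry scenario: exchangeability holds (delta = 0);
# covariate distributions and generating models keep the package defaults,
# calibrated to a ~34% marginal mastectomy rate, ~21% in situ share and
# ~77% of cases surviving the rule-out step.
n_cases: 5000
seed: 1
exchangeability_violation_delta: 0
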