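# Stress scenario: the exchangeability assumption is violated — being
# overdiagnosed shifts the mastectomy log-odds by +1 beyond what covariates
# explain, so the fill-up bounds are no longer guaranteed to cover the truth.
n_cases: 5000
seed: 1
exchangeability_violation_delta: 1.0
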