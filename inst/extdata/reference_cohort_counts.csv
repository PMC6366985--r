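cohort,n_total,n_idh_mutant,printed_pct
training,158,118,74.7
validation,102,77,75.5
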