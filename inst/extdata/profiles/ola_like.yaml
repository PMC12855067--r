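name: ola_like
daily_event_mean: 1.5
circadian_beta: 1.24
acrophase_h: 12
awakening_hazard: 3
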