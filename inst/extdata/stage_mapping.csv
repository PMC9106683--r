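label,stage
non-degraded,S0
nondegraded,S0
undegraded,S0
intact,S0
no degradation,S0
reference,S0
healthy,S0
very lightly degraded,S1
very light degradation,S1
initial cracking,S1
lightly degraded,S2
light degradation,S2
slightly degraded,S2
slight degradation,S2
moderately degraded,S3
moderate degradation,S3
heavily degraded,S4
heavy degradation,S4
severely degraded,S4
severe degradation,S4
extremely degraded,S5
extreme degradation,S5
bare soil,S5
bare patch,S5
black soil patch,S5
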