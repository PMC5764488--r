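# Exact rate equations, slow synaptic kinetics: oscillation suppressed
model = qif_fre
[parameters]
tau_m = 10
tau_d = 50
J = 21
Theta = 4
Delta = 0.3
[initial]
r0_hz = 5
v0 = 0
s0_hz = 5
[run]
duration_ms = 500
provenance = slow-synapse reference preset
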