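# Slow synapses driven by a periodic sinusoid-cubed stimulus (period 20 ms)
model = qif_fre
tau_m = 10
tau_d = 100
J = 21
Theta = 4
Delta = 0.3
forcing_type = sinusoid_cubed
forcing_base = 4
forcing_T = 20
duration_ms = 400
provenance = forced slow-synapse preset, T_theta = 20 ms
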