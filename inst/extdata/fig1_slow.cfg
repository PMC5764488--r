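# Wang-Buzsaki network, slow inhibitory synapses: oscillation suppressed
model = wb_net
N = 1000
I_bar = 0.5
sigma = 0.01
k = 6
tau_d = 50
tau_s = 2
duration_ms = 2000
provenance = conductance-based slow-synapse preset
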