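# Phase-diagram sweep, Lorentzian currents, relative heterogeneity delta = 0.06
model = wb_net
N = 300
I_bar = 0.166667
sigma = 0.01
k = 6
tau_d = 5
sweep_tau_d = 5,10,20,30,40,60
sweep_k = 2,6,10,14,18,22
sweep_direction = increasing
duration_ms = 900
provenance = reduced-scale amplitude sweep, delta = 0.06
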