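[neuron]
tau_m = 20
V_r = 10
theta_mean = 20
tau_ref = 5

[structure]
N = 1000
gamma = 0.80000000000000004
eps = 0.20000000000000001

[weights]
J_EE = 0.050000000000000003
J_IE = 0.050000000000000003
J_EI = -0.080000000000000002
J_II = -0.080000000000000002

[heterogeneity]
w_E = 0.10000000000000001
w_I = 0.10000000000000001

[drive]
mu = 15
mu0 = 15
sigma = 3
S0 = 0
f_s = 2

[sim]
duration = 2000
dt = 0.050000000000000003
transient = 500
n_trials = 2
master_seed = 1

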