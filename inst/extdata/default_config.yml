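nt1: 9.0
nt2: 9.0
nh1: 3.0
nh2: 3.0
n1: 900.0
n2: 900.0
box:
- 30.0
- 30.0
- 30.0
density: 3.0
n_steps: 300000.0
dt: 0.01
lambda: 0.5
initial: layered
energy_every: 100.0
frame_every: 1000.0
a_like: 25.0
a_unlike: 100.0
gamma: 4.5
sigma: 3.0
ks: 120.0
rs: 0.7
k_theta: 6.0
theta0: 3.1415927
pore_radius: 8.0
vesicle_radius: 8.0
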