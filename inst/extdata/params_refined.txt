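ka = 0.647
cl_pop = 15
v_pop = 862
theta_cl_alb = 0.122
theta_cl_bsa = 0.474
theta_cl_tac = -0.026
theta_v_alb = 0.101
omega2_cl = 0.127
omega2_v = 0.743
omega_cl_v = 0
sigma2_prop = 0.242
ref_alb = 4
ref_bsa = 1.7
ref_tac = 6
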