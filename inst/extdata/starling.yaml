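species: common starling
f: 10.5
l_w: 0.185
b_max: 0.39
m_b: 0.07
m_w: 0.0037
S_w_max: 0.02414
AR_max: 6.4
theta: 1.476548547187203
S_b: 0.0021
c_d_body: 0.24
c_d_fric_ref: 0.014
v_thresh: 11.619999999999999
c_l_max: 1.6
b_min: 0.078
I_b: 1.565e-05
I_wing: 1.455e-05
J: 0.0001528
mass_convention: total
friction: fixed
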