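species: peregrine falcon
f: 5.1
l_w: 0.284
b_max: 0.873
m_b: 0.528
m_w: 0.032
S_w_max: 0.0897
AR_max: 8.49
theta: 1.256637061435917
S_b: 0.004275
c_d_body: 0.14
c_d_fric_ref: 0.00935
v_thresh: 16.5
c_l_max: 1.6
b_min: 0.1746
I_b: 0.000448
I_wing: 0.0002966
J: 0.0025013
mass_convention: total
friction: fixed
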