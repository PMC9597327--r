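mu_max: 2.3999999999999999
K_d: 0.01
Q_min: 0.034000000000000002
Q_max: 0.12
U_max: 0.58999999999999997
K_N: 0.01
K_I: 50
n: 1.8999999999999999
ka_slope: 2.7400000000000002
ka_intercept: 0.20999999999999999
tfa_coeff: 3.6800000000000002
tfa_exponent: 1.3200000000000001
tfa_offset: 42.200000000000003
epa_content: 55
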