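state_dim: 1
fixed_point: 0.0
fail_bound: 0.05484443612947672
grid_half_n: 20
noise_sd: 0.013
timing: SS0
g: 9.8100000000000005
nominal_step_length: 1.02012604371928872
nominal_step_duration: 1.00115670309173677
sens_state: 1.32477555269108138
sens_pert: 1.32477555269108138
family: A
seed: 1862
a: 0.52837290019113159
b: 1.0
pert_min: -0.20000000000000001
pert_max: 0.20000000000000001
pert_spacing: 0.002
pert_grid:
- -0.20000000000000001
- -0.19800000000000001
- -0.19600000000000001
- -0.19400000000000001
- -0.192
- -0.19
- -0.188
- -0.186
- -0.184
- -0.182
- -0.17999999999999999
- -0.17799999999999999
- -0.17599999999999999
- -0.17399999999999999
- -0.17199999999999999
- -0.16999999999999998
- -0.16799999999999998
- -0.16599999999999998
- -0.16399999999999998
- -0.16199999999999998
- -0.15999999999999998
- -0.15799999999999997
- -0.156
- -0.154
- -0.152
- -0.15000000000000002
- -0.14800000000000002
- -0.14600000000000002
- -0.14400000000000002
- -0.14200000000000002
- -0.14000000000000001
- -0.13800000000000001
- -0.13600000000000001
- -0.13400000000000001
- -0.13200000000000001
- -0.13
- -0.128
- -0.126
- -0.124
- -0.122
- -0.12
- -0.11799999999999999
- -0.11599999999999999
- -0.11399999999999999
- -0.112
- -0.11
- -0.108
- -0.106
- -0.104
- -0.10199999999999999
- -0.09999999999999999
- -0.09799999999999999
- -0.09599999999999999
- -0.094
- -0.092
- -0.09
- -0.08800000000000002
- -0.08600000000000002
- -0.08400000000000002
- -0.08200000000000002
- -0.08000000000000002
- -0.07800000000000001
- -0.07600000000000001
- -0.07400000000000001
- -0.07200000000000001
- -0.07000000000000001
- -0.068
- -0.066
- -0.064
- -0.062
- -0.06
- -0.058
- -0.05599999999999999
- -0.05400000000000001
- -0.052
- -0.05
- -0.048
- -0.046
- -0.044
- -0.042
- -0.03999999999999999
- -0.03800000000000001
- -0.036
- -0.034
- -0.032
- -0.03
- -0.028
- -0.026
- -0.02400000000000001
- -0.02200000000000001
- -0.02
- -0.018
- -0.016
- -0.014
- -0.012
- -0.01
- -0.00800000000000001
- -0.00600000000000001
- -0.004
- -0.002
- 0.0
- 0.002
- 0.004
- 0.00600000000000001
- 0.00800000000000001
- 0.01
- 0.012
- 0.014
- 0.016
- 0.018
- 0.02
- 0.02200000000000001
- 0.02400000000000001
- 0.026
- 0.028
- 0.03
- 0.032
- 0.034
- 0.036
- 0.03800000000000001
- 0.03999999999999999
- 0.042
- 0.044
- 0.046
- 0.048
- 0.05
- 0.052
- 0.05400000000000001
- 0.05599999999999999
- 0.058
- 0.06
- 0.062
- 0.064
- 0.066
- 0.068
- 0.07000000000000001
- 0.07200000000000001
- 0.07400000000000001
- 0.07600000000000001
- 0.07800000000000001
- 0.08000000000000002
- 0.08200000000000002
- 0.08400000000000002
- 0.08600000000000002
- 0.08800000000000002
- 0.09
- 0.092
- 0.094
- 0.09599999999999999
- 0.09799999999999999
- 0.09999999999999999
- 0.10199999999999999
- 0.104
- 0.106
- 0.108
- 0.11
- 0.112
- 0.11399999999999999
- 0.11599999999999999
- 0.11799999999999999
- 0.12
- 0.122
- 0.124
- 0.126
- 0.128
- 0.13
- 0.13200000000000001
- 0.13400000000000001
- 0.13600000000000001
- 0.13800000000000001
- 0.14000000000000001
- 0.14200000000000002
- 0.14400000000000002
- 0.14600000000000002
- 0.14800000000000002
- 0.15000000000000002
- 0.152
- 0.154
- 0.156
- 0.15799999999999997
- 0.15999999999999998
- 0.16199999999999998
- 0.16399999999999998
- 0.16599999999999998
- 0.16799999999999998
- 0.16999999999999998
- 0.17199999999999999
- 0.17399999999999999
- 0.17599999999999999
- 0.17799999999999999
- 0.17999999999999999
- 0.182
- 0.184
- 0.186
- 0.188
- 0.19
- 0.192
- 0.19400000000000001
- 0.19600000000000001
- 0.19800000000000001
- 0.20000000000000001
spatio_gain:
  T_state: 0.05
  T_pert: 0.12299242776059653
  L_state: -0.04
  L_pert: -0.13324179674064626

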