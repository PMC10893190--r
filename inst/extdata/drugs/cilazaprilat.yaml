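schema: ces1pbpk-drug-v1
name: cilazaprilat
is_metabolite: true
parent: cilazapril
mw_g_mol: 389.44
logp: -0.48
pka: 3.17
binding_protein: albumin
fu_b: 0.76
rb: 1
v_sys_l: 10.3517
k_lp: 1.28
k_gp: 1.22
k_kp: 1.42
k12_per_min: 0.00084
k21_per_min: 0.008
clint_k_ml_min: 75.48
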