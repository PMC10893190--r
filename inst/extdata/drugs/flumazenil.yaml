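schema: ces1pbpk-drug-v1
name: flumazenil
mw_g_mol: 303.29
logp: 1.64
pka: 0.86
binding_protein: albumin
fu_b: 0.6
rb: 1
v_sys_l: 24.054
k_lp: 2.57
k_gp: 2.71
k_kp: 2.41
cl_b_ml_min: 1120
k12_per_min: 0.0376
k21_per_min: 0.0427
peff_1e4_cm_s: 3.78
clint_k_ml_min: 1.67
pathways:
- enzyme: CES1
  clint_ml_min: 8169.9
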