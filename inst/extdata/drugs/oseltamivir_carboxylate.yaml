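schema: ces1pbpk-drug-v1
name: oseltamivir_carboxylate
is_metabolite: true
parent: oseltamivir
mw_g_mol: 284.35
logp: -1.3
pka: 4.19
binding_protein: albumin
fu_b: 0.97
rb: 1
v_sys_l: 160.729
k_lp: 1.71
k_gp: 1.89
k_kp: 1.91
clint_k_ml_min: 438.5
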