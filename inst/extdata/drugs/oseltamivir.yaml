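schema: ces1pbpk-drug-v1
name: oseltamivir
metabolite: oseltamivir_carboxylate
mw_g_mol: 312.4
logp: 0.36
pka: 7.7
binding_protein: albumin
fu_b: 0.58
rb: 1
v_sys_l: 61.289
k_lp: 1.19
k_gp: 1.12
k_kp: 1.29
ka_per_min: 0.061
clint_k_ml_min: 1357.95
pathways:
- enzyme: CES1
  clint_ml_min: 20255.4
  metabolite: oseltamivir_carboxylate
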