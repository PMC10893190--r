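schema: ces1pbpk-drug-v1
name: temocapril
metabolite: temocaprilat
mw_g_mol: 476.6
logp: 2.102
pka: 2.8
binding_protein: albumin
fu_b: 0.3
rb: 1
f: 0.65
v_sys_l: 15.398
k_lp: 2.82
k_gp: 3.17
k_kp: 2.47
ka_per_min: 0.065
clint_k_ml_min: 110.2
pathways:
- enzyme: CES1
  clint_ml_min: 5359.7
  metabolite: temocaprilat
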