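ank_kp: 6.73641826862276627
ank_kd: 0.0
ank_ref: 0.07681942447754112
vel_g: 3.88232957035772053
kne_kp: 3.82359575014043651
kne_kd: 0.487830708413721
bal_kp: 6.76629480314825482
bal_kd: 2.0377325815323446
hip_kp: 1.72464212109636139
hip_kd: 0.0
sol_gf: 0.0
gas_gf: 0.39491633490912703
vas_gf: 0.41271746794714231
glu_c: 0.04623954119957514
ham_share: 0.18804350039942011
po_sol: 0.40955423229660687
ds_t: 0.15636871862268578
hfl_sw: 0.24267257239941711
hfl_gl: 0.19456072074710445
bfsh_sw: 0.16190416180402278
ham_sw: 0.11612818734248875
glu_sw: 0.20649675611333163
vas_sw: 0.28894933672635498
ta_sw: 0.51454595203184406
t_sw: 0.20892536235240278
min_st: 0.16347302776131764
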