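[pools]
A_tot = 2.3999999999999999
Nc_tot = 0.5
Nm_tot = 0.5
C_tot = 10

[glut]
T_glut_ce = 0.12
T_glut_en = 0.5
T_glut_ea = 0.29999999999999999
K_glut = 8

[hexokinase]
k_hk_n = 0.10000000000000001
k_hk_a = 0.12
K_glc_hk = 0.050000000000000003
K_I_atp = 1
n_H = 4
K_atp_hk = 0.10000000000000001

[glycolysis]
k_pk_n = 0.080000000000000002
k_pk_a = 0.080000000000000002
K_adp_pk = 0.050000000000000003
K_nad_pk = 0.050000000000000003

[ldh]
k_ldh_f_n = 5
k_ldh_r_n = 0.0030000000000000001
k_ldh_f_a = 6
k_ldh_r_a = 0.00029999999999999997

[mito]
V_mito_n = 0.089999999999999997
V_mito_a = 0.0080000000000000002
K_pyr = 0.050000000000000003
K_o2 = 0.01
K_adp = 0.10000000000000001
K_nadm = 0.10000000000000001
n_atp_ox = 14.800000000000001
o2_per_pyr = 3
k_etc_n = 0.20000000000000001
k_etc_a = 0.050000000000000003
n_atp_nadh = 2.5

[shuttle]
k_shuttle_n = 4
k_shuttle_a = 1

[mct]
T_mct_n = 0.20000000000000001
T_mct_a = 0.10000000000000001
T_mct_ec = 0.25
K_mct = 1

[oxygen]
PS_o2_n = 0.050000000000000003
PS_o2_a = 0.02

[sodium]
k_pump_n = 0.0114
k_pump_a = 0.00089999999999999998
g_leak_n = 0.0041999999999999997
g_leak_a = 0.00059999999999999995
na_e = 150
g_ampa = 2
V_eaat = 0.14999999999999999
K_glu = 0.02
s_na = 3
f_glu_recycle = 0.5
k_glu_decay = 0.10000000000000001

[creatine_kinase]
k_ck_f = 0.10000000000000001
k_ck_r = 0.0089999999999999993

[glycogen]
V_gs = 0.0050000000000000001
K_gs = 0.10000000000000001
GLY_max = 12
K_atp_gs = 0.10000000000000001
V_gp = 0.02
K_gp = 1
K_camp = 1

[noradrenaline]
k_ne = 1
k_camp_basal = 0.0050000000000000001
k_camp_deg = 0.10000000000000001

[capillary]
GLC_art = 4.7999999999999998
LAC_art = 0.59999999999999998
O2_art = 8
F_0 = 0.59999999999999998

[drive]
j_rel_rest = 0.0001

[volumes]
v_n = 0.45000000000000001
v_a = 0.25
v_e = 0.20000000000000001
v_c = 0.10000000000000001

[switches]
transport_off = false
mito_off = false

# initial guess for the resting-state root solve
[resting_guess]
Na_n = 8
GLC_n = 1
G6P_n = 0.10000000000000001
PYR_n = 0.10000000000000001
LAC_n = 0.80000000000000004
NADHc_n = 0.0050000000000000001
NADHm_n = 0.12
ATP_n = 2.2000000000000002
PCr_n = 5
O2_n = 3
Na_a = 14
GLC_a = 1.1000000000000001
G6P_a = 0.10000000000000001
PYR_a = 0.14999999999999999
LAC_a = 1.3
NADHc_a = 0.01
NADHm_a = 0.12
ATP_a = 2.2000000000000002
PCr_a = 5
O2_a = 5
GLY_a = 7
cAMP_a = 0.050000000000000003
GLU_e = 3.0000000000000001e-05
GLC_e = 1.2
LAC_e = 1
GLC_c = 4.5
LAC_c = 0.69999999999999996
O2_c = 7.5

# solved resting state under the resting drive (residual < 1e-11 mM/s)
[resting_state]
Na_n = 8.5410350337440857
GLC_n = 2.379056583966304
G6P_n = 0.080565126455214547
PYR_n = 0.012098243716742165
LAC_n = 0.70040183480726337
NADHc_n = 0.0032497586093585846
NADHm_n = 0.071094984639679393
ATP_n = 2.0341314369441923
PCr_n = 3.3350037976069604
O2_n = 6.9057276247435802
Na_a = 12.942292618304592
GLC_a = 2.3615074327874486
G6P_a = 0.11981352450392219
PYR_a = 0.50404679566139921
LAC_a = 0.96265891495697331
NADHc_a = 0.0018741832902701618
NADHm_a = 0.11551627145780798
ATP_a = 2.366692172340167
PCr_a = 8.6477280255028042
O2_a = 7.4340692310564647
GLY_a = 8.1091782387575488
cAMP_a = 0.049999999999999996
GLU_e = 2.6006922808798466e-05
GLC_e = 2.5196793305648457
LAC_e = 0.72841316590351701
GLC_c = 4.746850620338428
LAC_c = 0.61666355185216626
O2_c = 7.686276773851576
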