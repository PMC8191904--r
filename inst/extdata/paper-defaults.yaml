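# Default parameter set for the slurry methane-emission model.
# Units are the model's native units: kg slurry, g COD, g S, g N, degC, d.
# provenance: main-text = value stated in the model description;
# placeholder = literature-informed default (supplementary values not
# available), overridable per scenario.
version: 1
defaults: none
duration: 365
output_dt: 1
n_warmup_cycles: 5
groups:
  - id: m1                      # cold-adapted (Methanolobus psychrophilus)
    T_min: -2.0
    T_opt: 18.0
    T_max: 25.0
    yield: 0.05               # provenance: main-text
    k_d: 0.02
    KS_coef: 1.0                # provenance: main-text (default 1)
    C_X_in: 0.001               # provenance: main-text
    is_sulfate_reducer: no
    provenance: placeholder     # cardinal temperatures
  - id: m2                      # intermediate (Methanosarcina soligelidi)
    T_min: 0.0
    T_opt: 28.0
    T_max: 38.0
    yield: 0.05               # provenance: main-text
    k_d: 0.02
    KS_coef: 1.0
    C_X_in: 0.001
    is_sulfate_reducer: no
    provenance: placeholder
  - id: m3                      # mesophilic (Methanobrevibacter/Methanocorpusculum)
    T_min: 10.0
    T_opt: 37.0
    T_max: 45.0
    yield: 0.05               # provenance: main-text
    k_d: 0.02
    KS_coef: 1.0
    C_X_in: 0.01                # provenance: main-text (10x other groups)
    is_sulfate_reducer: no
    provenance: placeholder
  - id: m4                      # optimum midway between m3 and m5 (main-text rule)
    T_min: 15.0
    T_opt: 43.5
    T_max: 52.0
    yield: 0.05               # provenance: main-text
    k_d: 0.02
    KS_coef: 1.0
    C_X_in: 0.001
    is_sulfate_reducer: no
    provenance: placeholder
  - id: m5                      # thermophilic (Methanosarcina thermophila)
    T_min: 20.0
    T_opt: 50.0
    T_max: 58.0
    yield: 0.05               # provenance: main-text
    k_d: 0.02
    KS_coef: 1.0
    C_X_in: 0.001
    is_sulfate_reducer: no
    provenance: placeholder
# q_max,opt omitted per group: filled by the linear rule
# 0 at 0 degC -> 8 g_COD-S g_COD-B^-1 d^-1 at 40 degC (main-text).
include_sulfate_reducer: no
hydrolysis:                     # provenance: main-text
  T_min: 0.0
  T_opt: 50.0
  T_max: 60.0
  alpha_opt: 0.02               # 1/d
ks_params:                      # provenance: placeholder
  k1: 1.0                       # g COD-S per kg at 0 degC
  k2: 0.05                      # 1/degC
influent:
  C_Sp_in: 47.7                 # g COD-S/kg = 80 g VS/kg * 0.42 * 1.42; placeholder VS
  C_VFA_in: 1.0                 # provenance: placeholder
  C_SO4_in: 0.2                 # g SO4-S/kg; placeholder
  C_H2S_in: 0.0
  C_TAN_in: 2.0                 # g N/kg; placeholder
management:                     # provenance: main-text
  F_in: 1000.0                  # kg/d
  M_max: 33333.0                # kg
  f_resid: 0.1
  a_enrich: 0.0
  mode: threshold
transfer:                       # provenance: placeholder
  area: 33.0                    # m2
  kL_O2: 100.0                  # kg m-2 d-1
  kH_O2: 24.2                   # atm kg g-1 (0.208/kH = saturated O2, g/kg)
  kL_H2S: 10.0                  # kg m-2 d-1 (1 cm film turned over daily)
  pO2: 0.208
productivities: {}              # derived from yields (acetate-like substrate)
speciation:                     # provenance: placeholder
  pKa_NH4_A: 0.09018
  pKa_NH4_B: 2729.92
  pKa_H2S_25: 7.02
  dH_H2S: 22100.0               # J/mol
solver:
  method: lsoda
  rtol: 1.0e-8
  atol: 1.0e-6
  gate_eps: 0.01
forcings:                       # provenance: main-text (default 20 degC, pH 7)
  times: 0.0
  temp_c: 20.0
  ph: 7.0
vs_conversion:                  # provenance: main-text
  f_degradable: 0.42
  cod_per_vs: 1.42
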