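geometry:
  shape: bovine_cylinder
  height: 7.0
  outer_radius: 10.0
  aspect_ratio: 1.0
  np_fraction: 0.5
  n_sectors: 16.0
  n_np_rings: 2.0
  n_iaf_rings: 2.0
  n_oaf_rings: 2.0
  n_axial: 4.0
  trans_thickness: 0.4
  bulge: 0.0
materials:
  OAF:
    region_label: OAF
    E_m: 0.018
    nu: 0.24
    beta_m: 3.4
    k0: 0.0047
    M: 5.75
    c0F: 44.0
    E_f: 15.6
    lambda0: 1.028
    theta: 31.0
    beta_f: 4.0
    phi0_s: 0.3
  AFtrans:
    region_label: AFtrans
    E_m: 0.023
    nu: 0.2
    beta_m: 2.8
    k0: 0.0036
    M: 4.6
    c0F: 50.0
    E_f: 10.3
    lambda0: 1.025
    theta: 38.5
    beta_f: 4.0
    phi0_s: 0.3
  IAF:
    region_label: IAF
    E_m: 0.026
    nu: 0.16
    beta_m: 2.1
    k0: 0.0025
    M: 3.5
    c0F: 55.0
    E_f: 6.9
    lambda0: 1.023
    theta: 41.5
    beta_f: 4.0
    phi0_s: 0.3
  NPtrans:
    region_label: NPtrans
    E_m: 0.045
    nu: 0.2
    beta_m: 1.5
    k0: 0.0016
    M: 2.71
    c0F: 217.0
    E_f: 3.0
    lambda0: 1.02
    theta: 44.5
    beta_f: 4.0
    phi0_s: 0.2
  NP:
    region_label: NP
    E_m: 0.065
    nu: 0.24
    beta_m: 0.95
    k0: 0.00056
    M: 3.79
    c0F: 379.0
    E_f: .na.real
    lambda0: .na.real
    theta: .na.real
    beta_f: .na.real
    phi0_s: 0.2
  CEP:
    region_label: CEP
    E_m: 0.305
    nu: 0.18
    beta_m: 0.29
    k0: 0.00056
    M: 3.79
    c0F: 248.0
    E_f: .na.real
    lambda0: .na.real
    theta: .na.real
    beta_f: .na.real
    phi0_s: 0.4
  VB:
    region_label: VB
    E_m: 10000.0
    nu: 0.3
    beta_m: 0.0
    k0: 0.00056
    M: 0.0
    c0F: 0.0
    E_f: .na.real
    lambda0: .na.real
    theta: .na.real
    beta_f: .na.real
    phi0_s: 0.4
environment:
  bath_osmolarity: 300.0
  temperature: 310.0
  osmotic_coefficient: 1.0
mode: multigen
omega: 3.0
dH: 0.0
preload: 0.0
solver:
  tol_rel: 1.0e-08
  tol_abs: 1.0e-08
  max_iter: 40.0
  max_halvings: 6.0
  fd_h: 1.0e-06
seed: 1
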