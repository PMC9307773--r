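# Example biofilter scenario configuration: the bistable-column parameter set
# (compost/wood-chip packing, toluene, lab-scale column).
kinetics:
  v_max: 0.3          # g substrate / g biomass / h
  k_s: 0.05           # g/m^3
  k_i: 2.7            # g/m^3
  mu_max: 0.1         # 1/h
  decay_a: 0.0014     # 1/h
  yield_y: 0.5        # g/g
  rho_bio: 1.0e+5      # g/m^3
transport:
  henry_h: 0.25
  diffusivity_m2_s: 1.5e-10   # converted to m^2/h on load
  superficial_velocity: 3.63  # m/h
  porosity_eps: 0.55
  rho_bulk: 555               # kg compost / m^3 bed
  area_a: 0.95                # m^2 / kg compost
  bed_height: 0.25            # m
  bed_diameter: 0.10          # m
nitrogen:
  n_org: 14.98        # g N / kg compost
  k_min: 0.00007      # 1/h
  k_uptake: 0.0022    # 1/h
  k_n: 0.5            # g N / kg compost
  f_n: 0.126          # g N / g biomass
  n_inorg_0: 0.916    # g N / kg compost
discretization:
  n_axial: 25
  n_biofilm: 10
  solver_rtol: 1.0e-6
  solver_atol: 1.0e-9
  growth_concentration_mode: gas_literal
  advection_scheme: collocation
x0: 0.003             # g biomass / kg compost
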