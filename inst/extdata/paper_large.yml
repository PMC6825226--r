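# Large-scaffold configuration: a 5 mm diameter x 2 mm analogue sampled by
# 3 x 3 isometric RVEs of 0.4 x 0.4 x 2.0 mm, perfused at 3 mL/min.
# The bioreactor channel dimensions are placeholders (the published design
# lives in cited prior work): the channel is taken as press-fit, i.e. equal
# to the scaffold diameter.
fluid:
  mu_mpa_s: 1.0
  rho_kg_m3: 1000
geometry:
  source: generator
  porosity: 0.85
  mean_pore_diameter_um: 150
  shape: [500, 500, 200]
  voxel_size_um: 10
  seed: 1
rve:
  grid: [3, 3]
  xy_um: 400
micro:
  inlet_velocity_um_s: 500   # used for the per-RVE permeability solves
  tol: 1.0e-4
macro:
  channel_shape: cylinder
  channel_diameter_um: 5000  # placeholder: press-fit channel
  porous_diameter_um: 5000
  flow_rate_ml_min: 3
  resolution: 20
  outlet_pressure_pa: 0
wss:
  bin_width_mpa: 5
  max_mpa: 100
  weighting: area
  bands:
    - [0.11, 10]     # osteogenic differentiation window
    - [0.55, 24]     # mineralized matrix production window
    - [10, 30]       # mineralization window
subregions:
  n_regions: 5
  width_um: 40
direct:
  memory_budget_gb: 4
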