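# Validation-study configuration: a small scaffold analogue
# (1.5 x 1.5 x 1.0 mm box at 10 um voxels) with a single central RVE of
# 0.5 x 0.5 x 1.0 mm, perfused at a superficial velocity of 500 um/s.
# The synthetic scaffold stands in for a salt-leached silk-fibroin
# scaffold: porosity and pore size are typical for that material class.
fluid:
  mu_mpa_s: 1.0        # culture medium dynamic viscosity
  rho_kg_m3: 1000
geometry:
  source: generator
  porosity: 0.85
  mean_pore_diameter_um: 150
  shape: [150, 150, 100]
  voxel_size_um: 10
  seed: 1
rve:
  grid: [1, 1]
  xy_um: 500
micro:
  inlet_velocity_um_s: 500
  tol: 1.0e-4
macro:
  channel_shape: box    # matches the direct model's no-slip side walls
  channel_diameter_um: 1500
  resolution: 20
  outlet_pressure_pa: 0
wss:
  bin_width_mpa: 5
  max_mpa: 100
  weighting: area
  bands:
    - [10, 30]
subregions:
  n_regions: 5
  width_um: 50          # 5 x 0.05 mm annuli tile the 0.5 mm RVE footprint
direct:
  memory_budget_gb: 4
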