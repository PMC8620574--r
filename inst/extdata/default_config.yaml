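# petflow default configuration (schema_version 1)
# Units are stated per field; all values feed the SI-internal model.
schema_version: 1

domain:
  width_m: 0.0672          # tissue rectangle width [m]
  height_m: 0.0609         # tissue rectangle height [m]
  tumor_diameter_m: 0.023  # tumor disc diameter [m], centred
  grid_spacing_m: 2.24e-4  # target cell size [m] (~300 x 270 cells)

vasculature:
  mvd_tumor_m_per_m2: 8000     # capillary length density in tumor [m/m^2]
  mvd_normal_m_per_m2: 3000    # capillary length density in normal tissue [m/m^2]
  n_parent_vessels: 4          # parent vessels (top, bottom, two mid-height)
  parent_radius_m: 40.0e-6     # parent lumen radius [m]
  capillary_radius_m: 5.0e-6   # capillary lumen radius [m]
  inlet_pressure_mmHg: 25      # blood pressure, left parent ends [mmHg]
  outlet_pressure_mmHg: 10     # blood pressure, right parent ends [mmHg]
  branch_step_m: 1.2e-3        # characteristic capillary segment [m]
  seed: 1                      # generator RNG seed

imaging:
  pixel_size_m: 20.0e-6    # physical size of one image pixel [m]
  threshold: 0.5           # binarization threshold on [0,1] (or "otsu")
  clahe_clip: 0.01         # CLAHE normalized clip limit [-]
  clahe_tiles: [8, 8]      # CLAHE tile grid [rows, cols]
  min_component_px: 30     # despeckle: drop components smaller than this [px]
  render_noise_sigma: 10   # synthetic render: Gaussian noise sd [0-255]
  render_background: 40    # synthetic render: background green level [0-255]

flow:
  viscosity_Pa_s: 3.0e-3     # blood viscosity [Pa s]
  boundary_pressure_Pa: 0    # outer Dirichlet interstitial pressure [Pa]
  tol: 1.0e-6                # coupled fixed-point relative L2 tolerance [-]
  max_iter: 50               # coupled fixed-point iteration cap

params:
  tumor_kinetics_factor: 10  # tumor L3/L4 multiplier over normal [-]

transport:
  dt_s: 1.0                          # time step [s]
  t_end_s: 3600                      # simulated duration [s]
  output_times_s: [60, 120, 180, 600, 1800, 3600]  # reporting times [s]
  n_substeps: 4                      # RK4 kinetic substeps per dt
  conservative_convection: false     # flux-form upwind instead of v.grad C
  aif:
    kind: biexponential
    A_mol_per_m3: 100     # AIF amplitude [mol/m^3]
    tau_rise_s: 30        # bolus rise time constant [s]
    tau_wash_s: 1800      # washout time constant [s]
    # or: kind: csv, path: aif.csv  (columns t_s, Cp_mol_per_m3)
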