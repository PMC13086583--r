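# Default run configuration. Physical quantities carry units in key names
# (um, s, pN; torques pN um; angles rad).
seed: 1

channel:
  half_width_um: 1            # W: square channel cross-section is 2W x 2W
  truncation_factor: 20       # truncated length in units of W
  panel_size_um: 0.25         # boundary-element panel edge (<= W/4)
  viscosity_pN_s_per_um2: 1.0e-3

bacterium:
  motor_torque_pN_um: 2       # flagellar motor torque Gamma_M
  body_length_um: 5           # l_B
  alpha: 1.5                  # dipole ratio, l_D = alpha * l_B
  swim_speed_um_s: 20         # U_s

puck:
  radius_um: 10
  diffusivity_rad2_s: 6.0e-5  # thermal rotational diffusivity D_Theta
  temperature_K: 298.15

bath:
  concentration_per_ml: 6.0e+8
  curvature_radius_um: 50     # R_c of the clockwise swimming circles
  body_length_um: 3
  force_pN: 0.2               # per-collision tangential force scale
  collision_rate_per_perimeter: 0.06   # s^-1 um^-1 of perimeter
  contact_time_s: 0.3
  rectification_c: 1.5

simulation:
  dt_s: 0.1                   # 10 frames per second acquisition
  duration_s: 600
  angle_noise_rad: 0.01       # measurement noise (not an experimental claim)
  position_noise_um: 0.2

inference:
  lambda: null                # null -> computed by the `lambda` command
  reversal_bandwidth_um: 1
  prereversal_fraction: 0.9
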