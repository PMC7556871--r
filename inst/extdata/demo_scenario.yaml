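# Demo end-to-end scenario: wild-type-like saltatory migration with
# coupled energetics, autophagic flux, puncta density and leading-process
# profiling, at sizes that complete in well under a minute.
seed: 1
stages: [migration, energy, flux, density, profile]
migration:
  n_cells: 12
  frame_interval: 30    # s
  duration: 3600        # s
  v_mig: 116.2          # um/h
  v_noise: 10           # um/h
  duty_cycle: 0.478
  mean_phase_mig: 480   # s
  turn_sd: 0.15         # rad/frame
phases:
  v_on: 40              # um/h
  v_off: 20             # um/h
  smooth_window: 3
  min_dwell_frames: 2
energy:
  n_cells: 10
  r0: 1.0
  drop_rate: 1.5e-5     # ratio units / s
  recovery_rate: 6.0e-5
  r_floor: 0.7
  noise_sd: 0.01
  den_level: 1000
flux:
  n_cells: 6
  frac_dual_mig: 0.355
  frac_dual_stat: 0.444
  n_puncta: 200
  psf_sigma: 1.5
  peak_snr: 5
  image_shape: [192, 192]
density:
  n_cells: 10
  density_stat: 0.5     # puncta / um^2
  rel_density_mig: 0.66
  area_um2: 120
profile:
  soma_mean: 47.7
  bin_means: [58.43, 40.0, 58.3]
  pixel_size: 0.5       # um/px
  bin_width_um: 20
  noise_sd: 5
  n_images: 5
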