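# Default octfocus configuration: 810 nm SD-OCT at NA ~0.1 in the eye,
# two-band retina phantom, session disturbances of a fixated subject.
params:
  refractive_index_n: 1.38
  rayleigh_length_zR: 26        # um
  beam_quality_M2: 1.5
  center_wavelength_lambda0: 810  # nm
  pixel_wavelength_spacing: 0.049 # nm
  spectral_resolution: 0.06       # nm (FWHM)
  mu_backscatter: 1.0
  mu_oct_attenuation: 0.001       # 1/um
  axial_pixel_pitch: 3            # um/pixel
  n_depth_pixels: 384
  n_lateral_ascans: 64
  diopter_to_depth: 370           # um/D
  noise_floor_sigma: 0.02
phantom:
  n_depth_pixels: 384
  inner_band_center: 140          # px
  outer_band_center: 220          # px
  inner_band_width: 7             # px (Gaussian sd)
  outer_band_width: 5
  inner_band_amplitude: 0.9
  outer_band_amplitude: 1.0
  background_level: 0.05
ou_motion:
  mean_reversion_theta: 5         # 1/s
  stationary_sigma: 53.2          # um
  dt: 0.04                        # s
ou_defocus:
  mean_reversion_theta: 5
  stationary_sigma: 0.27          # D
  dt: 0.04
agent:
  action_scale: 1.0               # D per unit tanh output
  Nb: 15                          # reward sliding-window half-range, px
  M: 4                            # lateral sub-regions
  train_steps: 1200
  rng_seed: 1
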