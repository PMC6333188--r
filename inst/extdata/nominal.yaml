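# Nominal configuration of the analytic virtual-source model: the fitted
# parameter set of the modeled 6 MV linac (leaf bank rotation 9 mrad, air
# gap 0.089 mm, leaf density 18.5 g/cm^3, primary source FWHM 1.05 mm,
# mean energies 1.6 / 0.7 MeV) with a single open leaf on the axis.
# Omitted keys keep the package defaults of nominal_config().
beam:
  z_target_distal: 1.1
  z_filter_distal: 15.9
  z_mlc_top: 30.0
  z_isocenter: 100.0
  sad: 100.0
leaf:
  projected_width: 5.0
  height: 90.0
  lbrot: 9.0
  air_gap: 0.089
  tg_enabled: no
  tg_width: 0.4
  density: 18.5
  composition:
    W: 0.96
    Ni: 0.03
    Fe: 0.01
aperture: CCCCCOCCCCC
primary:
  type: gaussian
  fwhm: 1.05
  mean_energy: 1.6
  energy_mode: mono
  angular_type: focal
  angular_spread: 23.0
secondary:
  enabled: yes
  fwhm: 30.0
  mean_energy: 0.7
  energy_mode: mono
  angular_type: focal
  angular_spread: 100.0
  weight: 0.05
raytrace:
  path_mode: oblique
  quadrature: 0.01
  margin: 5.0
  grid_step: 0.1
  grid_half: 15.0
generator:
  n_photons: 100000
  seed: 1
  focal_fwhm: 1.05
  primary_fraction: 0.95
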