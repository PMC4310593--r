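# Example run configuration: a small simulated imaging session.
# Geometry mirrors the acquisition protocol (0.625 um/px lateral, 1 um
# z-step); the field is trimmed to keep the example quick.
schema_version: 1
seed: 11
output_dir: ectishape-out
phantom:
  fov_width: 160       # um; 256 columns at 0.625 um/px
  fov_depth: 120       # um
  px_lateral: 0.625
  px_axial: 1.0
  keratin_thickness: 10
  noise_gaussian_sd: 5
  noise_poisson_scale: 0.1
boundary:
  baseline_depth: 60
  sine_amplitude: 12
  sine_period: 70
  bumps:
    - { center: 50, amplitude: 15, width: 10 }
    - { center: 110, amplitude: 12, width: 8 }
trace:
  sigma: 2
  low: 0.4
  high: 0.8
grid:
  n_normal: 3
  n_dysplastic: 3
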