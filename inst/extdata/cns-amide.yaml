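# Carbonyl/amide-region demo (1500-1700 cm-1): residual carboxylate, N-H
# deformation, adsorbed-water bending and amide C=O with staggered onsets
# (amide responds first, then water, then the carboxylate groups).
synthetic:
  bands:
    - {center: 1583, width: 10, shape: gaussian, base_amplitude: 0.7, delta_amplitude: 0.14, response: sigmoid, onset_T: 315, response_width: 6}
    - {center: 1596, width: 10, shape: gaussian, base_amplitude: 0.6, delta_amplitude: 0.0,  response: sigmoid, onset_T: 295, response_width: 6}
    - {center: 1635, width: 10, shape: gaussian, base_amplitude: 0.5, delta_amplitude: 0.12, response: sigmoid, onset_T: 295, response_width: 6}
    - {center: 1654, width: 10, shape: gaussian, base_amplitude: 1.0, delta_amplitude: 0.25, response: sigmoid, onset_T: 275, response_width: 6}
  t_min: 250
  t_max: 340
  t_step: 10
  nu_min: 1500
  nu_max: 1700
  nu_step: 4
  noise_sigma: 0
  seed: 1
region: [1500, 1700]
reference: first
baseline: linear_endpoints
normalization:
  mode: vector          # no internal-standard band inside this window
peaks:
  threshold_frac: 0.05
  sign_epsilon: 0.05
  min_separation: 8
slices: [1583, 1635]
output: noda2d-demo-amide
seed: 1
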