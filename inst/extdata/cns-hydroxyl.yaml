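# Hydrogen-bond stretching-region demo (2680-3780 cm-1): intrachain O(3)H..O(5)
# and amide N-H respond first, then intrachain O(2)H..O(6), then interchain
# hydrogen bonds (the most stable linkages respond last).
synthetic:
  bands:
    - {center: 3242, width: 30, shape: gaussian, base_amplitude: 0.8, delta_amplitude: -0.16, response: sigmoid, onset_T: 315, response_width: 6}
    - {center: 3270, width: 25, shape: gaussian, base_amplitude: 0.7, delta_amplitude: -0.14, response: sigmoid, onset_T: 300, response_width: 6}
    - {center: 3347, width: 25, shape: gaussian, base_amplitude: 0.9, delta_amplitude: -0.20, response: sigmoid, onset_T: 280, response_width: 6}
    - {center: 3374, width: 25, shape: gaussian, base_amplitude: 0.8, delta_amplitude: -0.18, response: sigmoid, onset_T: 280, response_width: 6}
    - {center: 3500, width: 60, shape: gaussian, base_amplitude: 0.4, delta_amplitude: 0.0,  response: sigmoid, onset_T: 295, response_width: 6}
  t_min: 250
  t_max: 340
  t_step: 10
  nu_min: 2680
  nu_max: 3780
  nu_step: 4
  noise_sigma: 0
  seed: 1
region: [2680, 3780]
reference: first
baseline: linear_endpoints
normalization:
  mode: vector
peaks:
  threshold_frac: 0.05
  sign_epsilon: 0.05
  min_separation: 16
slices: [3242, 3270]
output: noda2d-demo-hydroxyl
seed: 1
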