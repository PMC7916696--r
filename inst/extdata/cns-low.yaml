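# Fingerprint-region demo (900-1200 cm-1): cellulose backbone / C-N bands
# with staggered sigmoid response onsets along the 250-340 K trajectory.
synthetic:
  bands:
    - {center: 992,  width: 9,  shape: gaussian, base_amplitude: 0.8, delta_amplitude: 0.16, response: sigmoid, onset_T: 315, response_width: 6}
    - {center: 1021, width: 8,  shape: gaussian, base_amplitude: 0.6, delta_amplitude: 0.15, response: sigmoid, onset_T: 275, response_width: 6}
    - {center: 1031, width: 9,  shape: gaussian, base_amplitude: 1.0, delta_amplitude: 0.22, response: sigmoid, onset_T: 290, response_width: 6}
    - {center: 1055, width: 9,  shape: gaussian, base_amplitude: 1.0, delta_amplitude: 0.0,  response: sigmoid, onset_T: 295, response_width: 6}
    - {center: 1108, width: 10, shape: gaussian, base_amplitude: 0.7, delta_amplitude: 0.14, response: sigmoid, onset_T: 305, response_width: 6}
    - {center: 1161, width: 10, shape: gaussian, base_amplitude: 0.5, delta_amplitude: 0.10, response: sigmoid, onset_T: 305, response_width: 6}
  t_min: 250
  t_max: 340
  t_step: 10
  nu_min: 900
  nu_max: 1200
  nu_step: 4
  noise_sigma: 0
  seed: 1
region: [900, 1200]
reference: first
baseline: linear_endpoints
normalization:
  mode: band_area
  window: [1045, 1065]   # ~1055 cm-1 internal-standard band
peaks:
  threshold_frac: 0.05
  sign_epsilon: 0.05
  min_separation: 8
slices: [992, 1021, 1049]
output: noda2d-demo-low
seed: 1
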