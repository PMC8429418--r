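wavelength: 690.0
lesion_type: sclerotic
thresholds: reference
tissues:
  spinal_cord:
    optics:
      mu_a: 0.0216
      mu_s: 15.47
      g: 0.9
      'n': 1.41
    threshold:
      T_photons: 1.0e+17
      uptake_C: 0.13
      phi: 0.02
  bone:
    optics:
      mu_a: 0.01
      mu_s: 15.23
      g: 0.9
      'n': 1.56
    threshold:
      T_photons: 1.0e+18
      uptake_C: 0.3
      phi: 0.1
  metastasis:
    optics:
      mu_a: 0.01
      mu_s: 15.23
      g: 0.9
      'n': 1.56
    threshold:
      T_photons: 1.0e+19
      uptake_C: 0.7
      phi: 0.4
  muscle:
    optics:
      mu_a: 0.052
      mu_s: 7.356
      g: 0.93
      'n': 1.41
    threshold:
      T_photons: 1.0e+18
      uptake_C: 0.13
      phi: 0.1
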