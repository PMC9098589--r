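# Reference parameterization of the DAR-resolved ADC population PK model.
# fixed_effects: typical values; iiv: log-normal random-effect SDs (one
# shared kdec effect; fraction variabilities DAR0..DAR7, DAR8 back-
# calculated); residual_error: per-entity error models on the assay scale;
# lloq: censoring rules; regimen: the reference simulation regimen.
fixed_effects:
  f_nab: 0.071
  f_dar1: 0.085
  f_dar2: 0.175
  f_dar3: 0.218
  f_dar4: 0.199
  f_dar5: 0.142
  f_dar6: 0.071
  f_dar7: 0.028
  f_dar8: 0.009
  cl_adc: 0.392
  v_c: 3.37
  q: 0.543
  v_p: 2.54
  kdec1: 0.0565
  kdec2: 0.181
  kdec3: 0.340
  kdec4: 0.525
  kdec5: 0.751
  kdec6: 0.938
  cl_nab: 0.408
  cl_dm4: 240
  cl_medm4: 0.256
  fr_medm4: 0.0107
iiv:
  cl_adc: 0.469
  v_c: 0.245
  q: 0.529
  v_p: 0.605
  kdec: 0.202
  cl_nab: 0.345
  cl_dm4: 0.365
  cl_medm4: 0.654
  fr_medm4: 0.723
  f:
    DAR0: 0.418
    DAR1: 0.091
    DAR2: 0.091
    DAR3: 0.066
    DAR4: 0.059
    DAR5: 0.102
    DAR6: 0.132
    DAR7: 0.272
residual_error:
  a_adc: 1.03
  b_adc: 0.089
  b_dm4: 0.335
  b_medm4: 0.500
  b_nab: 0.260
  a_dar_average: 0.219
  a_prop:
    NAB: 9.93
    DAR1: 4.58
    DAR2: 3.48
    DAR3: 3.26
    DAR4: 2.53
    DAR5: 1.47
    DAR6: 0.798
    DAR7: 0.517
lloq:
  adc: 0.500
  dm4: 0.2
  medm4: 0.2
  nab_base: 1
  nab_dilution_threshold: 15
  nab_lloq_max: 9.60
regimen:
  dose_mg_m2: 100
  interval_days: 14
  n_cycles: 50
  infusion_hours: 1
  bsa: 1.8
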