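# Shared fixtures. Everything is generated in code; heavier shared objects
# are built once per test run and memoised here.

ref_params <- function() adc_params()

ref_model <- function() adc_model()

# single 100 mg/m^2 dose with long washout, moderate grid
single_dose_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_profile(ref_params(), adc_regimen(100, 14, 1),
                                 washout_days = 200, n_per_cycle = 600)
    }
    cache
  }
})

# 50-cycle Q2W reference simulation at the published typical values
q2w50_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_profile(ref_params(), adc_regimen(100, 14, 50),
                                 n_per_cycle = 2000)
    }
    cache
  }
})

# small single-cohort trial used by several stochastic tests
small_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      des <- trial_design(
        cohorts = tibble::tibble(cohort = "t", dose_mg_m2 = 100,
                                 interval_days = 14, n = 12,
                                 loading_dose_mg_m2 = NA_real_),
        dar_subset_n = 2, fixed_cycles = 4)
      cache <<- generate_trial(des, ref_model(), seed = 42)
    }
    cache
  }
})

# a noise-free single-subject dataset at the typical parameters
noiseless_trial <- function(n = 1, seed = 7) {
  model <- adc_model(
    params = adc_params(),
    iiv = adc_iiv(cl_adc = 0, v_c = 0, q = 0, v_p = 0, kdec = 0, cl_nab = 0,
                  cl_dm4 = 0, cl_medm4 = 0, fr_medm4 = 0,
                  f = c(DAR0 = 0, DAR1 = 0, DAR2 = 0, DAR3 = 0, DAR4 = 0,
                        DAR5 = 0, DAR6 = 0, DAR7 = 0)),
    residual = adc_residual(a_adc = 0, b_adc = 0, b_dm4 = 0, b_medm4 = 0,
                            b_nab = 0, a_dar_average = 0,
                            a_prop = c(NAB = 0, DAR1 = 0, DAR2 = 0, DAR3 = 0,
                                       DAR4 = 0, DAR5 = 0, DAR6 = 0, DAR7 = 0)),
    lloq = adc_lloq(adc = 1e-12, dm4 = 1e-12, medm4 = 1e-12,
                    nab_base = 1e-12, nab_dilution_threshold = 1e12,
                    nab_lloq_max = 1e-11))
  des <- trial_design(
    cohorts = tibble::tibble(cohort = "t", dose_mg_m2 = 100,
                             interval_days = 14, n = n,
                             loading_dose_mg_m2 = NA_real_),
    dar_subset_n = 0, fixed_cycles = 2,
    bsa_mean = 1.8, bsa_sd = 0)
  list(trial = generate_trial(des, model, seed = seed), model = model)
}
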