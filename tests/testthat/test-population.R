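test_that("individual sampling: degenerate IIV returns the typical subject", {
  iiv0 <- adc_iiv(cl_adc = 0, v_c = 0, q = 0, v_p = 0, kdec = 0, cl_nab = 0,
                  cl_dm4 = 0, cl_medm4 = 0, fr_medm4 = 0,
                  f = c(DAR0 = 0, DAR1 = 0, DAR2 = 0, DAR3 = 0, DAR4 = 0,
                        DAR5 = 0, DAR6 = 0, DAR7 = 0))
  p <- ref_params()
  set.seed(1)
  ind <- sample_individual(p, iiv0, n = 3)
  expect_equal(ind$cl_adc, rep(p$cl_adc, 3))
  expect_equal(ind$kdec6, rep(p$kdec[[6]], 3))
  expect_equal(ind$f_DAR8, rep(p$f[["DAR8"]], 3), tolerance = 1e-12)
})

test_that("individual sampling: log-sd matches omega and fractions close to 1", {
  set.seed(99)
  ind <- sample_individual(ref_params(), adc_iiv(), n = 4000)
  # geometric CV of CL_ADC reproduces its omega within Monte-Carlo error
  expect_equal(stats::sd(log(ind$cl_adc)), 0.469, tolerance = 0.03)
  expect_equal(stats::sd(log(ind$v_c)), 0.245, tolerance = 0.03)
  # one shared deconjugation random effect: perfectly correlated kdec draws
  expect_equal(stats::cor(log(ind$kdec1), log(ind$kdec6)), 1, tolerance = 1e-12)
  expect_equal(stats::sd(log(ind$kdec3)), 0.202, tolerance = 0.03)
  # every sampled fraction vector sums to one (DAR8 back-calculated)
  fsum <- rowSums(as.matrix(ind[paste0("f_DAR", 0:8)]))
  expect_true(all(abs(fsum - 1) < 1e-9))
  expect_true(all(ind$f_DAR8 >= 0))
})

test_that("residual error model: exactness, published sd, Monte-Carlo sd", {
  res <- adc_residual()
  # no-error spec returns the prediction
  res0 <- adc_residual(a_adc = 0, b_adc = 0)
  set.seed(2)
  expect_equal(residual_observe(10, "ADC", res0), 10)
  # combined ADC error at f = 10 ug/mL: sd = 1.03 + 0.089 * 10 = 1.92
  expect_equal(residual_sd(10, "ADC", res), 1.92, tolerance = 1e-12)
  expect_equal(residual_sd(100, "NAB", res), 26)
  expect_equal(residual_sd(3, "DARavg", res), 0.219)
  expect_equal(residual_sd(50, "PROP_DAR3", res), 3.26)
  # empirical sd over many draws matches a + b*f within 3%
  set.seed(3)
  draws <- residual_observe(rep(10, 10000), "ADC", res)
  expect_equal(stats::sd(draws - 10), 1.92, tolerance = 0.03)
})

test_that("LLOQ censoring, including the concentration-dependent NAB limit", {
  rule <- adc_lloq()
  # ADC below 0.500 ug/mL is censored and carries its limit
  r <- apply_lloq(0.4, "ADC", rule)
  expect_true(r$blq)
  expect_equal(r$lloq, 0.5)
  expect_true(is.na(r$value))
  # DM4 at 0.25 ng/mL is above the 0.2 ng/mL limit and retained
  r <- apply_lloq(0.25, "DM4", rule)
  expect_false(r$blq)
  expect_equal(r$value, 0.25)
  # NAB at 5 ug/mL with co-measured ADC of 100 ug/mL: dilution factor 7
  # inflates the limit to 7 ug/mL, so the observation is censored
  r <- apply_lloq(5, "NAB", rule, context_adc = 100)
  expect_true(r$blq)
  expect_gte(r$lloq, 7)
  # the NAB limit never exceeds the assay cap
  r <- apply_lloq(5, "NAB", rule, context_adc = 1e4)
  expect_equal(r$lloq, 9.60)
  # and never drops below the base limit
  r <- apply_lloq(5, "NAB", rule, context_adc = 1)
  expect_equal(r$lloq, 1)
  # DAR streams carry no limit
  expect_true(is.na(apply_lloq(0.01, "DARavg", rule)$lloq))
})

test_that("unit conversion uses per-entity molecular weights and round-trips", {
  expect_equal(convert_units(150, "ADC", "mass_to_molar"), 1.0)
  expect_equal(convert_units(0.78, "DM4", "mass_to_molar"), 0.001)
  expect_equal(convert_units(1, "NAB", "molar_to_mass"), 144.522)
  x <- c(0.03, 1.7, 250)
  for (e in c("ADC", "NAB", "DM4", "MeDM4")) {
    expect_equal(convert_units(convert_units(x, e, "mass_to_molar"), e,
                               "molar_to_mass"), x, tolerance = 1e-12)
  }
  expect_error(convert_units(1, "XYZ"), "unknown entity")
})
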