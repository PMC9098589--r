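test_that("rate matrix encodes the deconjugation cascade and payload release", {
  p <- ref_params()
  A <- build_rate_matrix(p)

  # DAR1 central feeds the DM4 pool at kdec1
  expect_equal(A["DM4", "DAR1_c"], 0.0565)
  # cascade coupling DARn -> DARn-1 at kdec_n, tied rates for DAR7/DAR8
  expect_equal(A["DAR0_c", "DAR1_c"], p$kdec[["kdec1"]])
  expect_equal(A["DAR6_c", "DAR7_c"], p$kdec[["kdec6"]])
  expect_equal(A["DAR7_c", "DAR8_c"], p$kdec[["kdec6"]])

  # with all kdec = 0 the DM4 row receives no inflow at all
  p0 <- update_params(p, kdec1 = 0, kdec2 = 0, kdec3 = 0, kdec4 = 0,
                      kdec5 = 0, kdec6 = 0)
  A0 <- build_rate_matrix(p0)
  expect_true(all(A0["DM4", setdiff(colnames(A0), "DM4")] == 0))

  # column sums over the antibody block: antibody mass leaves a central
  # DARi column only through proteolytic elimination (deconjugation and
  # distribution are internal transfers); payload release into the DM4 row
  # adds one molar equivalent per deconjugation event on top
  ab <- 1:18
  for (i in 1:8) {
    col <- paste0("DAR", i, "_c")
    expect_equal(sum(A[ab, col]), -p$cl_adc / p$v_c, tolerance = 1e-12)
    expect_equal(A["DM4", col], unname(p$kdec[[i]]))
  }
  expect_equal(sum(A[ab, "DAR0_c"]), -p$cl_nab / p$v_c, tolerance = 1e-12)
  # peripheral columns conserve mass exactly
  for (i in 0:8) expect_equal(sum(A[ab, paste0("DAR", i, "_p")]), 0)
})

test_that("parameter validation rejects non-positive and non-finite values", {
  expect_error(adc_params(v_c = -1), "positive")
  expect_error(adc_params(cl_adc = NaN), "positive")
  expect_error(adc_params(fr_medm4 = 1.2), "0, 1")
  expect_error(adc_params(f_dar3 = -0.1), "non-negative")
  # kdec7/kdec8 always follow kdec6
  p <- update_params(adc_params(), kdec6 = 0.5)
  expect_equal(unname(p$kdec[7:8]), c(0.5, 0.5))
})

test_that("dose splitting follows the administered DAR fractions", {
  p <- ref_params()
  ds <- dose_split(p, 1000, 1)
  # 21.8% of the administered dose enters the DAR3 compartment
  expect_equal(ds$amount_nmol[ds$species == "DAR3"], 218, tolerance = 3e-3)
  expect_equal(sum(ds$amount_nmol), 1000, tolerance = 1e-9)
  expect_equal(sum(ds$rate_nmol_day) * (1 / 24), 1000, tolerance = 1e-9)
  expect_true(all(dose_split(p, 0)$rate_nmol_day == 0))
})

test_that("clearance decomposition reproduces the published table", {
  ct <- clearance_table(ref_params())
  get <- function(dar, col) ct[[col]][ct$dar == dar]
  # proteolytic clearance is shared; deconjugation clearance is kdec_i * V_c
  expect_equal(signif(get("DAR1", "deconjugation_cl"), 3), 0.190)
  expect_equal(signif(get("DAR1", "global_cl"), 3), 0.582)
  expect_equal(signif(get("DAR2", "global_cl"), 3), 1.00)
  expect_equal(signif(get("DAR4", "deconjugation_cl"), 3), 1.77)
  expect_equal(signif(get("DAR5", "global_cl"), 3), 2.92)
  expect_equal(signif(get("DAR>=6", "deconjugation_cl"), 3), 3.16)
  expect_equal(signif(get("DAR>=6", "global_cl"), 3), 3.55)
  # without deconjugation the global clearance collapses to CL_ADC
  p0 <- update_params(ref_params(), kdec1 = 0, kdec2 = 0, kdec3 = 0,
                      kdec4 = 0, kdec5 = 0, kdec6 = 0)
  expect_true(all(clearance_table(p0)$global_cl == p0$cl_adc))
})

test_that("derived outputs: sums, proportions and average DAR", {
  base <- stats::setNames(rep(0, 9), paste0("C_DAR", 0:8))
  as_row <- function(v) tibble::as_tibble(as.data.frame(t(v)))
  # only DAR2 mass: average DAR 2, DAR2 proportion 100%
  x <- as_row(replace(base, "C_DAR2", 1.5))
  d <- derived_outputs(x)
  expect_equal(d$dar_average, 2)
  expect_equal(d$prop_DAR2, 100)
  expect_equal(d$C_ADC, 1.5)
  # equal molar DAR0 and DAR4: average 2, proportions 50/50
  x <- as_row(replace(base, c("C_DAR0", "C_DAR4"), 0.3))
  d <- derived_outputs(x)
  expect_equal(d$dar_average, 2)
  expect_equal(d$prop_NAB, 50)
  expect_equal(d$prop_DAR4, 50)
  expect_equal(d$C_TAB, 0.6)
  # zero total antibody: undefined, flagged, not NaN
  d0 <- derived_outputs(as_row(base))
  expect_false(d0$dar_defined)
  expect_true(is.na(d0$dar_average))
})

test_that("simulated profiles: linearity, superposition, zero dose", {
  p <- ref_params()
  times <- seq(0, 28, by = 0.25)
  reg1 <- adc_regimen(100, 14, 1)
  reg2 <- adc_regimen(200, 14, 1)
  s1 <- simulate_profile(p, reg1, times = times)
  s2 <- simulate_profile(p, reg2, times = times)
  cols <- c(paste0("C_DAR", 0:8), "C_ADC", "C_NAB", "C_DM4", "C_MeDM4")
  for (cl in cols) {
    expect_equal(s2[[cl]], 2 * s1[[cl]], tolerance = 1e-8)
  }
  # average DAR is dose-invariant (ratio of linear functionals)
  expect_equal(s2$dar_average, s1$dar_average, tolerance = 1e-8)

  # superposition: two doses equal the sum of shifted single doses
  regm <- adc_regimen(100, 14, 2)
  sm <- simulate_profile(p, regm, times = times)
  shift <- simulate_amounts(p, reg1$events, pmax(times - 14, 0))
  shift[, times < 14] <- 0
  direct <- simulate_amounts(p, reg1$events, times) + shift
  multi <- simulate_amounts(p, regm$events, times)
  expect_equal(max(abs(multi - direct)) / max(direct), 0, tolerance = 1e-8)
  expect_equal(sm$C_ADC[times < 14], s1$C_ADC[times < 14], tolerance = 1e-8)

  s0 <- simulate_profile(p, adc_regimen(0, 14, 1), times = times)
  expect_true(all(s0$C_TAB == 0) && all(s0$C_DM4 == 0))
  expect_true(all(is.na(s0$dar_average)))
})

test_that("matrix-exponential path agrees with an adaptive ODE integrator", {
  skip_if_not_installed("deSolve")
  p <- ref_params()
  A <- build_rate_matrix(p)
  reg <- adc_regimen(100, 14, 2)
  ev <- reg$events
  rate_vec <- function(t) {
    u <- rep(0, 20)
    act <- ev$time < t & t < ev$time + ev$duration_day
    for (d in which(act)) {
      u[1:9] <- u[1:9] + p$f * ev$amount_nmol[d] / ev$duration_day[d]
    }
    u
  }
  rhs <- function(t, y, parms) list(as.vector(A %*% y) + rate_vec(t))
  times <- sort(unique(c(seq(0, 28, by = 0.5), ev$time, ev$time + ev$duration_day)))
  num <- deSolve::lsoda(rep(0, 20), times, rhs, NULL,
                        rtol = 1e-11, atol = 1e-12)[, -1]
  ref <- t(simulate_amounts(p, ev, times))
  expect_lt(max(abs(num - ref)) / max(ref), 1e-6)
})

test_that("antibody and payload molar balances close", {
  mb <- mass_balance(ref_params(), adc_regimen(100, 14, 3))
  expect_true(all(mb$rel_error < 1e-3))
  # long horizon, loading-dose regimen
  mb2 <- mass_balance(ref_params(),
                      adc_regimen(100, 14, 6, loading_dose_mg_m2 = 170),
                      t_end = 120)
  expect_true(all(mb2$rel_error < 1e-3))
})

test_that("average DAR is non-increasing between doses", {
  sim <- q2w50_sim()
  dar <- sim$dar_average
  t <- sim$time
  ev <- attr(sim, "events")
  # check within each of a few interdose intervals, after the infusion ends
  for (cy in c(1, 2, 5, 49)) {
    k <- which(t > ev$time[cy] + ev$duration_day[cy] + 1e-9 &
                 t <= ev$time[cy] + 14)
    expect_true(all(diff(dar[k]) <= 1e-9))
  }
  expect_true(all(dar >= 0 & dar <= 8, na.rm = TRUE))
})
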