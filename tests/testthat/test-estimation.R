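# one subject's rows from the cached small trial
one_subject <- function(id = 1) {
  trial <- small_trial()
  trial$observations[trial$observations$id == id, ]
}

test_that("individual likelihood: exact normal and censored (M3) terms", {
  res <- adc_residual()
  d <- one_subject()
  sub <- d[d$evid == 1, ][1, ]
  reg_rows <- d[d$evid == 1, ]
  p <- ref_params()

  # single observation placed exactly at the model prediction
  t_obs <- 3
  pred <- predict_entities(
    p, tibble::tibble(time = reg_rows$time, amount_nmol = reg_rows$amt,
                      duration_day = reg_rows$amt / reg_rows$rate),
    t_obs, "ADC")$pred
  s <- res$a_adc + res$b_adc * pred
  toy <- dplyr::bind_rows(
    reg_rows,
    tibble::tibble(id = 1, time = t_obs, evid = 0L, amt = NA_real_,
                   rate = NA_real_, mdv = 0L, entity = "ADC", dv = pred,
                   blq = FALSE, lloq = NA_real_))
  expect_equal(individual_loglik(p, toy, res), -0.5 * log(2 * pi * s^2),
               tolerance = 1e-12)

  # a censored row with the limit far above the prediction contributes ~0
  toy$blq[toy$evid == 0] <- TRUE
  toy$dv[toy$evid == 0] <- NA_real_
  toy$lloq[toy$evid == 0] <- pred * 100
  expect_equal(individual_loglik(p, toy, res), 0, tolerance = 1e-10)

  # three-observation toy: M3 total matches a brute-force quadrature
  # oracle (numeric integration of the residual density below the limit)
  mix <- dplyr::bind_rows(
    reg_rows,
    tibble::tibble(id = 1, time = c(2, 5, 9), evid = 0L, amt = NA_real_,
                   rate = NA_real_, mdv = c(0L, 1L, 1L), entity = "DM4",
                   dv = c(1.1, NA, NA), blq = c(FALSE, TRUE, TRUE),
                   lloq = c(NA, 0.2, 0.35)))
  predm <- predict_entities(
    p, tibble::tibble(time = reg_rows$time, amount_nmol = reg_rows$amt,
                      duration_day = reg_rows$amt / reg_rows$rate),
    c(2, 5, 9), "DM4")$pred
  sdm <- res$b_dm4 * predm
  oracle_cens <- function(f, s, lim) {
    log(stats::integrate(function(y) stats::dnorm(y, f, s), -Inf, lim,
                         rel.tol = 1e-12)$value)
  }
  oracle <- stats::dnorm(1.1, predm[1], sdm[1], log = TRUE) +
    oracle_cens(predm[2], sdm[2], 0.2) + oracle_cens(predm[3], sdm[3], 0.35)
  expect_equal(individual_loglik(p, mix, res), oracle, tolerance = 1e-8)
})

test_that("importance-sampling marginal likelihood matches 1-D quadrature", {
  d <- one_subject()
  d <- d[d$evid == 1 | d$entity == "ADC", ]
  model <- ref_model()
  est <- "cl_adc"
  # quadrature oracle over the single random effect
  subs <- darpk:::prep_fast(darpk:::prep_subjects(d))
  om <- model$iiv$omega[["cl_adc"]]
  lt <- log(model$params$cl_adc)
  ll_eta <- Vectorize(function(eta) {
    phi <- stats::setNames(lt + eta, est)
    darpk:::safe_loglik(darpk:::params_from_phi(model$params, phi),
                        subs[[1]], model$residual)$ll
  })
  grid <- seq(-5 * om, 5 * om, length.out = 61)
  cmax <- max(ll_eta(grid))
  quad <- log(stats::integrate(function(e)
    exp(ll_eta(e) - cmax) * stats::dnorm(e, 0, om), -5 * om, 5 * om,
    rel.tol = 1e-10)$value) + cmax

  pl <- population_loglik(d, model, estimate = est, mc_size = 2000, seed = 4)
  expect_equal(pl$loglik, quad, tolerance = 0.02)
  expect_equal(pl$ofv, -2 * pl$loglik)

  # an extra needless parameter worsens BIC through its penalty
  pl2 <- population_loglik(d, model, estimate = c("cl_adc", "q"),
                           mc_size = 2000, seed = 4)
  expect_gt(pl2$bic, pl$bic - 2) # likelihood barely moves, penalty grows
  expect_gt(pl2$n_params, pl$n_params)
})

test_that("empirical Bayes: prior mode without data, recovery, shrinkage", {
  model <- ref_model()
  est <- c("cl_adc", "v_c")

  # subject with dose events but no observations: eta at the prior mode
  d <- one_subject()
  doses_only <- d[d$evid == 1, ]
  eb0 <- empirical_bayes(doses_only, model, estimate = est)
  expect_equal(unname(unlist(eb0[paste0("eta_", est)])), c(0, 0))

  # noiseless subject simulated at a known eta is recovered
  eta_true <- c(cl_adc = 0.30, v_c = -0.20)
  p_i <- update_params(adc_params(), cl_adc = 0.392 * exp(0.30),
                       v_c = 3.37 * exp(-0.20))
  reg <- adc_regimen(100, 14, 2)
  times <- make_sampling_schedule(reg, rich_cycles = 1)
  pr <- predict_entities(p_i, reg$events, times, c("ADC", "NAB"))
  tiny <- adc_residual(a_adc = 1e-4, b_adc = 0.002, b_nab = 0.002)
  dd <- dplyr::bind_rows(
    tibble::tibble(id = 1, time = reg$events$time, evid = 1L,
                   amt = reg$events$amount_nmol,
                   rate = reg$events$amount_nmol / reg$events$duration_day,
                   mdv = 1L, entity = "DOSE", dv = NA_real_, blq = FALSE,
                   lloq = NA_real_),
    tibble::tibble(id = 1, time = pr$time, evid = 0L, amt = NA_real_,
                   rate = NA_real_, mdv = 0L, entity = pr$entity, dv = pr$pred,
                   blq = FALSE, lloq = NA_real_))
  m_tiny <- adc_model(adc_params(), adc_iiv(), tiny, adc_lloq())
  eb <- empirical_bayes(dd, m_tiny, estimate = est, maxit = 4000)
  expect_equal(eb$eta_cl_adc, eta_true[["cl_adc"]], tolerance = 1e-3)
  expect_equal(eb$eta_v_c, eta_true[["v_c"]], tolerance = 1e-3)

  # shrinking omega pulls the noisy-eta estimate monotonically toward zero
  m_noisy <- adc_model(adc_params(), adc_iiv(), adc_residual(), adc_lloq())
  mags <- vapply(c(1, 0.4, 0.1), function(sc) {
    iiv <- adc_iiv(cl_adc = 0.469 * sc, v_c = 0.245 * sc)
    abs(empirical_bayes(dd, adc_model(adc_params(), iiv, adc_residual(),
                                      adc_lloq()),
                        estimate = est)$eta_cl_adc)
  }, numeric(1))
  expect_true(all(diff(mags) < 0))
})

test_that("SAEM is deterministic given a seed and fits noise-free data", {
  # determinism contract on a small trial and short schedule
  trial <- small_trial()
  d <- trial$observations[trial$observations$id %in% 1:4, ]
  st <- saem_settings(n_explore = 8, n_smooth = 4, seed = 5)
  f1 <- fit_saem(d, init = ref_model(), settings = st)
  f2 <- fit_saem(d, init = ref_model(), settings = st)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$trajectories, f2$trajectories)

  # near-noiseless, no-IIV data: displaced fixed effects converge back
  nt <- noiseless_trial(n = 6, seed = 8)
  d0 <- nt$trial$observations
  d0 <- d0[d0$evid == 1 | d0$entity %in% c("ADC", "NAB"), ]
  small_res <- adc_residual(a_adc = 0.02, b_adc = 0.01, b_nab = 0.01)
  init <- adc_model(
    update_params(adc_params(), cl_adc = 0.392 * 1.25, cl_nab = 0.408 / 1.25),
    adc_iiv(cl_adc = 0.1, v_c = 0.1, q = 0.1, v_p = 0.1, cl_nab = 0.1),
    small_res, adc_lloq())
  fit <- fit_saem(d0, init = init, estimate = c("cl_adc", "v_c", "cl_nab"),
                  settings = saem_settings(n_explore = 50, n_smooth = 25,
                                           seed = 9),
                  estimate_residual = FALSE)
  expect_equal(unname(fit$theta[["cl_adc"]]), 0.392, tolerance = 0.02)
  expect_equal(unname(fit$theta[["cl_nab"]]), 0.408, tolerance = 0.02)
  expect_equal(unname(fit$theta[["v_c"]]), 3.37, tolerance = 0.02)
  # with no inter-individual variability the omegas collapse toward the floor
  expect_lt(fit$omega[["cl_adc"]], 0.05)

  # tidy/glance accessors
  td <- tidy(fit)
  expect_setequal(unique(td$type), c("theta", "omega", "residual"))
  expect_equal(nrow(glance(fit)), 1)
  expect_true(is.logical(glance(fit)$converged))
})
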