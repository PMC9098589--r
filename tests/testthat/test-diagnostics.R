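# diagnostics run against the true generating model on small virtual
# trials; heavier calibration checks live in the acceptance suite

diag_trial <- function(n = 30, seed = 21) {
  generate_trial(recovery_design(n, dar_subset_n = 0), adc_model(),
                 seed = seed)
}

test_that("residuals: zero-noise data give zero iWRES, misfit is visible", {
  nt <- noiseless_trial(n = 2, seed = 31)
  d <- nt$trial$observations
  d <- d[d$evid == 1 | d$entity %in% c("ADC", "NAB"), ]
  # residual spec with small nonzero sd so weighting is defined
  model <- adc_model(adc_params(), adc_iiv(),
                     adc_residual(a_adc = 0.1, b_adc = 0.05, b_nab = 0.05),
                     adc_lloq())
  rt <- pwres_iwres(d, model, nsim = 50, seed = 1,
                    estimate = c("cl_adc", "v_c"))
  # not exactly zero: with (a + b*f) error the -log sd term shifts the MAP
  # a fraction of a percent off the generating parameters
  expect_lt(max(abs(rt$iwres)), 0.15)

  # doubled clearance: individual residuals become systematically biased
  bad <- adc_model(update_params(adc_params(), cl_adc = 2 * 0.392),
                   adc_iiv(cl_adc = 0.05, v_c = 0.05, q = 0.05, v_p = 0.05,
                           kdec = 0.05, cl_nab = 0.05, cl_dm4 = 0.05,
                           cl_medm4 = 0.05, fr_medm4 = 0.05),
                   adc_residual(a_adc = 0.1, b_adc = 0.05, b_nab = 0.05),
                   adc_lloq())
  d_adc <- d[d$evid == 1 | d$entity == "ADC", ]
  rt_bad <- pwres_iwres(d_adc, bad, nsim = 50, seed = 1,
                        estimate = c("v_c", "q"))
  expect_gt(abs(mean(rt_bad$iwres)), 0.5)
})

test_that("PWRES is approximately standardized under the true model", {
  trial <- diag_trial(n = 25, seed = 22)
  d <- trial$observations
  d <- d[d$evid == 1 | (d$entity == "ADC" & !d$blq), ]
  rt <- pwres_iwres(d, adc_model(), nsim = 300, seed = 2,
                    estimate = c("cl_adc", "v_c", "q", "v_p"))
  expect_equal(stats::var(rt$pwres), 1, tolerance = 0.25)
  expect_equal(mean(rt$pwres), 0, tolerance = 0.15)
})

test_that("pc-VPC: identical designs need no correction; mixed doses collapse", {
  # all subjects share one design (equal BSA, same schedule): the typical
  # predictions coincide, so the prediction-correction factor within a bin
  # of identical times is identically 1
  des0 <- trial_design(
    cohorts = tibble::tibble(cohort = "flat", dose_mg_m2 = 100,
                             interval_days = 14, n = 10,
                             loading_dose_mg_m2 = NA_real_),
    dar_subset_n = 0, fixed_cycles = 1, bsa_sd = 0)
  trial <- generate_trial(des0, adc_model(), seed = 23)
  v <- pc_vpc(trial, adc_model(), entity = "ADC", nsim = 40, bins = 6,
              seed = 3, time_range = c(0, 14))
  expect_s3_class(v, "adc_vpc")
  subs <- darpk:::prep_fast(darpk:::prep_subjects(
    trial$observations[trial$observations$evid == 1 |
                         trial$observations$entity == "ADC", ]))
  pt <- darpk:::fast_pred(adc_model()$params, subs[[1]])
  pt2 <- darpk:::fast_pred(adc_model()$params, subs[[2]])
  expect_equal(pt, pt2, tolerance = 1e-12)

  # mixed 5-190 mg/m2 cohorts: corrected observed medians collapse onto
  # one band; the uncorrected values spread over the dose range
  des <- trial_design(
    cohorts = tibble::tibble(cohort = c("lo", "hi"),
                             dose_mg_m2 = c(5, 190), interval_days = 14,
                             n = c(10, 10), loading_dose_mg_m2 = NA_real_),
    dar_subset_n = 0, fixed_cycles = 1, bsa_sd = 0)
  mixed <- generate_trial(des, adc_model(), seed = 24)
  obm <- mixed$observations
  obm <- obm[obm$evid == 0 & obm$entity == "ADC" & !obm$blq, ]
  spread_raw <- stats::sd(log(obm$dv))
  vm <- pc_vpc(mixed, adc_model(), entity = "ADC", nsim = 40, bins = 6,
               seed = 4)
  # corrected percentiles sit inside the band for most bins even though the
  # doses span a 38-fold range
  expect_gte(mean(vm$within), 0.7)
  expect_gt(spread_raw, 1) # raw mixture is wildly dispersed
})

test_that("NPDE collapses to a normalized percentile for one observation", {
  trial <- diag_trial(n = 6, seed = 25)
  d <- trial$observations
  keep_first_obs <- function(df) {
    dplyr::slice_head(dplyr::group_by(df[df$evid == 0 &
                                           df$entity == "ADC" &
                                           !df$blq, ], .data$id), n = 1)
  }
  d1 <- dplyr::bind_rows(d[d$evid == 1, ], dplyr::ungroup(keep_first_obs(d)))
  nsim <- 400
  nd <- npde(d1, adc_model(), nsim = nsim, seed = 5, entities = "ADC")
  # oracle: rank of the observation among its simulated replicates
  subs <- darpk:::prep_fast(darpk:::prep_subjects(d1))
  sp <- darpk:::simulate_population(subs, adc_model(), nsim, seed = 5)
  for (j in seq_along(subs)) {
    y <- subs[[j]]$obs$dv
    S <- as.numeric(sp$sims[[j]])
    pd <- (sum(S < y) + 0.5 * sum(S == y)) / nsim
    pd <- min(max(pd, 1 / (2 * nsim)), 1 - 1 / (2 * nsim))
    expect_equal(nd$npde[nd$id == subs[[j]]$id], stats::qnorm(pd),
                 tolerance = 1e-9)
  }
})

test_that("NPDE flags halved variability as underdispersion", {
  trial <- diag_trial(n = 25, seed = 26)
  d <- trial$observations
  d <- d[d$evid == 1 | (d$entity == "ADC" & !d$blq), ]
  wide <- adc_model(adc_params(),
                    adc_iiv(cl_adc = 0.469 * 3, v_c = 0.245 * 3,
                            q = 0.529 * 3, v_p = 0.605 * 3, kdec = 0.606,
                            cl_nab = 1.04, cl_dm4 = 1.10, cl_medm4 = 1.96,
                            fr_medm4 = 2.17),
                    adc_residual(), adc_lloq())
  # data generated at the true omegas but checked against a model whose
  # omegas are tripled: the NPDE variance collapses below 1; conversely the
  # true data against halved omegas overdisperses
  nd_wide <- npde(d, wide, nsim = 300, seed = 6, entities = "ADC")
  expect_lt(npde_summary(nd_wide)$variance, 0.9)
  halfo <- adc_model(adc_params(),
                     adc_iiv(cl_adc = 0.469 / 2, v_c = 0.245 / 2,
                             q = 0.529 / 2, v_p = 0.605 / 2, kdec = 0.101,
                             cl_nab = 0.172, cl_dm4 = 0.182,
                             cl_medm4 = 0.327, fr_medm4 = 0.361),
                     adc_residual(), adc_lloq())
  nd_narrow <- npde(d, halfo, nsim = 300, seed = 6, entities = "ADC")
  expect_gt(npde_summary(nd_narrow)$variance, 1.1)
})

test_that("GOF report bundles residual tables and is deterministic", {
  trial <- diag_trial(n = 6, seed = 27)
  d <- trial$observations
  d <- d[d$evid == 1 | d$entity %in% c("ADC", "NAB"), ]
  g1 <- gof_report(d, adc_model(), nsim = 60, seed = 7,
                   estimate = c("cl_adc", "v_c"))
  g2 <- gof_report(d, adc_model(), nsim = 60, seed = 7,
                   estimate = c("cl_adc", "v_c"))
  expect_identical(g1$residuals, g2$residuals)
  expect_s3_class(g1$plots$obs_vs_pred, "ggplot")
  expect_true(all(c("mean_iwres", "sd_pwres") %in% names(g1$summary)))
  # slope of obs on individual predictions is ~1 for self-simulated data
  ok <- g1$residuals[!g1$residuals$blq & g1$residuals$entity == "ADC", ]
  sl <- stats::coef(stats::lm(dv ~ 0 + ipred, data = ok))[[1]]
  expect_equal(sl, 1, tolerance = 0.05)
  expect_error(gof_report(d[d$evid == 1, ], adc_model()), "empty")
})
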