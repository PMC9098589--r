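test_that("sampling schedules have the rich/sparse template structure", {
  q2w <- adc_regimen(100, 14, 6)
  t_q2w <- make_sampling_schedule(q2w)
  expect_true(all(t_q2w < 6 * 14))
  expect_true(all(t_q2w >= 0))
  # rich cycles carry a full profile, sparse cycles a trough only
  in_cycle <- function(tt, cy, tau) tt[tt >= (cy - 1) * tau & tt < cy * tau]
  expect_gte(length(in_cycle(t_q2w, 1, 14)), 8)
  expect_gte(length(in_cycle(t_q2w, 4, 14)), 8)
  expect_lte(length(in_cycle(t_q2w, 2, 14)), 2)
  expect_lte(length(in_cycle(t_q2w, 5, 14)), 2)

  q3w <- adc_regimen(100, 21, 3)
  t_q3w <- make_sampling_schedule(q3w, rich_cycles = 1)
  # troughs of consecutive sparse cycles are one 21-day interval apart
  troughs <- t_q3w[t_q3w > 21]
  expect_equal(diff(troughs), 21)
})

test_that("default virtual trial matches the emulated study layout", {
  trial <- generate_trial(trial_design(), adc_model(), seed = 1)
  obs <- trial$observations[trial$observations$evid == 0, ]
  expect_equal(length(unique(trial$observations$id)), 254)
  expect_equal(sum(trial$subjects$dar_subset), 13)
  # five measured quantities: four concentration streams everywhere,
  # DAR streams only in the subset, DAR8 proportion never emitted
  expect_setequal(unique(obs$entity[obs$id %in%
    trial$subjects$id[!trial$subjects$dar_subset]]),
    c("ADC", "NAB", "DM4", "MeDM4"))
  expect_false("PROP_DAR8" %in% obs$entity)
  expect_true(all(c("DARavg", "PROP_NAB", "PROP_DAR7") %in% obs$entity))
  # every BLQ row carries its LLOQ; dose events precede observations
  expect_true(all(!is.na(obs$lloq[obs$blq])))
  first_dose <- tapply(trial$observations$time[trial$observations$evid == 1],
                       trial$observations$id[trial$observations$evid == 1], min)
  first_obs <- tapply(obs$time, obs$id, min)
  expect_true(all(first_obs > first_dose[names(first_obs)]))

  # BLQ ordering matches the study: ADC lowest, DM4 and NAB highest
  bs <- blq_summary(trial)
  frac <- stats::setNames(bs$blq_frac, bs$entity)
  expect_lt(frac[["ADC"]], 0.05)
  expect_gt(frac[["DM4"]], 0.25)
  expect_gt(frac[["NAB"]], 0.2)
  expect_lt(frac[["ADC"]], frac[["MeDM4"]])
  expect_lt(frac[["MeDM4"]], frac[["DM4"]])

  # determinism: the same seed reproduces the table exactly
  trial2 <- generate_trial(trial_design(), adc_model(), seed = 1)
  expect_identical(trial$observations, trial2$observations)
  trial3 <- generate_trial(
    trial_design(cohorts = default_cohorts()[default_cohorts()$n > 100, ],
                 dar_subset_n = 5),
    adc_model(), seed = 2)
  expect_false(identical(trial$observations, trial3$observations))
})

test_that("degenerate generator reproduces the typical predictions exactly", {
  nt <- noiseless_trial()
  obs <- nt$trial$observations[nt$trial$observations$evid == 0, ]
  sub <- nt$trial$subjects
  reg <- adc_regimen(100, 14, sub$n_cycles[1], bsa = sub$bsa[1])
  pred <- predict_entities(adc_params(), reg$events, obs$time,
                           entities = unique(obs$entity))
  key <- paste(obs$time, obs$entity)
  expect_equal(obs$dv, pred$pred[match(key, paste(pred$time, pred$entity))],
               tolerance = 1e-10)
})

test_that("observed average-DAR streams decline from ~3.3 toward ~1 over cycles", {
  trial <- small_trial()
  obs <- trial$observations
  dar <- obs[obs$entity == "DARavg" & obs$evid == 0, ]
  expect_gt(nrow(dar), 10)
  early <- dar$dv[dar$time < 0.5]
  late <- dar$dv[dar$time > 10 & dar$time < 14.5]
  expect_equal(mean(early), 3.3, tolerance = 0.15)
  expect_lt(mean(late), 1.8)
  # empty design errors
  expect_error(generate_trial(trial_design(
    cohorts = tibble::tibble(cohort = character(), dose_mg_m2 = numeric(),
                             interval_days = numeric(), n = integer(),
                             loading_dose_mg_m2 = numeric()),
    dar_subset_n = 0), adc_model(), seed = 1), "empty")
})
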