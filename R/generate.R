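#' Entity codes of the observation table
#'
#' String entity codes with a numeric alias for NONMEM-style interop.
#'
#' @return A tibble with columns `entity`, `cmt` (numeric alias) and
#'   `units`.
#' @export
entity_codes <- function() {
  tibble::tibble(
    entity = c("ADC", "NAB", "DM4", "MeDM4", "DARavg",
               "PROP_NAB", paste0("PROP_DAR", 1:7)),
    cmt = 1:13,
    units = c("ug/mL", "ug/mL", "ng/mL", "ng/mL", "", rep("%", 8))
  )
}

#' Predicted observations on the assay scale for one individual
#'
#' Simulates the individual system at the requested times and returns the
#' model prediction of every requested entity stream on its observation
#' scale (ADC and NAB in ug/mL, DM4 and MeDM4 in ng/mL, average DAR
#' dimensionless, proportions in percent).
#'
#' @param params individual [adc_params()].
#' @param events dose-event tibble (or [adc_regimen()]).
#' @param times observation times (days), need not be sorted.
#' @param entities entity codes from [entity_codes()].
#' @return A tibble `time`, `entity`, `pred`. DAR streams are `NA` where
#'   the total antibody concentration is zero.
#' @export
predict_entities <- function(params, events, times,
                             entities = c("ADC", "NAB", "DM4", "MeDM4")) {
  ut <- sort(unique(times))
  x <- simulate_amounts(params, events, ut)
  conc <- tibble::tibble(time = ut)
  for (i in 0:8) conc[[paste0("C_DAR", i)]] <- x[i + 1, ] / params$v_c / 1000
  conc <- derived_outputs(conc)
  conc$C_DM4 <- x["DM4", ] / params$v_dm4 / 1000
  conc$C_MeDM4 <- x["MeDM4", ] / params$v_medm4 / 1000

  grab <- function(e) {
    switch(e,
      ADC = convert_units(conc$C_ADC, "ADC", "molar_to_mass"),
      NAB = convert_units(conc$C_NAB, "NAB", "molar_to_mass"),
      DM4 = convert_units(conc$C_DM4, "DM4", "molar_to_mass"),
      MeDM4 = convert_units(conc$C_MeDM4, "MeDM4", "molar_to_mass"),
      DARavg = conc$dar_average,
      PROP_NAB = conc$prop_NAB,
      {
        if (!grepl("^PROP_DAR[1-7]$", e)) stop("unknown entity: ", e, call. = FALSE)
        conc[[sub("PROP_", "prop_", e)]]
      })
  }
  out <- dplyr::bind_rows(lapply(entities, function(e) {
    tibble::tibble(time = ut, entity = e, pred = grab(e))
  }))
  out[match(paste(rep(times, length(entities)),
                  rep(entities, each = length(times))),
            paste(out$time, out$entity)), ]
}

#' Generate a virtual trial
#'
#' Draws a complete synthetic study from the population model: cohort
#' assignment and body-surface area, individual parameters (log-normal
#' inter-individual variability with the shared deconjugation random
#' effect and back-calculated DAR8 fraction), per-subject dosing and
#' rich/sparse sampling, residual error on the assay scale, and
#' lower-limit-of-quantification censoring (including the
#' concentration-dependent NAB limit). The DAR streams (average DAR and
#' relative proportions of NAB and DAR1--DAR7; DAR8 is never emitted) are
#' produced for a random subset of `design$dar_subset_n` subjects.
#'
#' The generator is deterministic given `(design, model, seed)`: subject
#' draws use a per-subject seed derived from `seed`.
#'
#' @param design an [trial_design()] object.
#' @param model an [adc_model()] bundle of true parameters.
#' @param seed integer seed.
#' @return An object of class `adc_trial`: a list with `observations`
#'   (the long observation/dose-event table), `subjects` (the
#'   true-parameter ledger, one row per subject) and `design`.
#' @examples
#' \donttest{
#' trial <- generate_trial(trial_design(), adc_model(), seed = 1)
#' dplyr::count(trial$observations, entity)
#' }
#' @export
generate_trial <- function(design = trial_design(), model = adc_model(),
                           seed = 1) {
  stopifnot(inherits(design, "adc_design"), inherits(model, "adc_model"))
  cohorts <- design$cohorts[design$cohorts$n > 0, ]
  if (nrow(cohorts) == 0) stop("empty design", call. = FALSE)
  n_total <- sum(cohorts$n)

  set.seed(seed %% .Machine$integer.max)
  dar_ids <- sort(sample.int(n_total, design$dar_subset_n))
  cohort_of <- rep(seq_len(nrow(cohorts)), cohorts$n)

  conc_entities <- c("ADC", "NAB", "DM4", "MeDM4")
  dar_entities <- c("DARavg", "PROP_NAB", paste0("PROP_DAR", 1:7))
  units <- stats::setNames(entity_codes()$units, entity_codes()$entity)

  subj_rows <- vector("list", n_total)
  obs_rows <- vector("list", n_total)

  for (id in seq_len(n_total)) {
    set.seed((seed + 7919L * id) %% .Machine$integer.max)
    ch <- cohorts[cohort_of[id], ]
    bsa <- min(max(stats::rnorm(1, design$bsa_mean, design$bsa_sd),
                   design$bsa_range[1]), design$bsa_range[2])
    n_cycles <- if (!is.null(design$fixed_cycles)) design$fixed_cycles else
      sample_cycle_count(1, design$median_cycles, design$max_cycles)
    reg <- adc_regimen(ch$dose_mg_m2, ch$interval_days, n_cycles,
                       infusion_hours = design$infusion_hours, bsa = bsa,
                       loading_dose_mg_m2 =
                         if (is.na(ch$loading_dose_mg_m2)) NULL
                         else ch$loading_dose_mg_m2)
    ind <- sample_individual(model$params, model$iiv, n = 1)
    ind$id <- id
    ind$cohort <- ch$cohort
    ind$dose_mg_m2 <- ch$dose_mg_m2
    ind$interval_days <- ch$interval_days
    ind$n_cycles <- n_cycles
    ind$bsa <- bsa
    ind$dar_subset <- id %in% dar_ids
    p_i <- params_from_row(model$params, ind)

    times <- make_sampling_schedule(reg, design$rich_cycles)
    entities <- if (id %in% dar_ids) c(conc_entities, dar_entities) else conc_entities
    pred <- predict_entities(p_i, reg$events, times, entities)
    pred <- pred[!is.na(pred$pred), ]
    pred$dv_obs <- residual_observe(pred$pred, pred$entity, model$residual)

    # censoring: NAB limit depends on the co-measured ADC observation
    adc_at <- pred$dv_obs[pred$entity == "ADC"][
      match(pred$time, pred$time[pred$entity == "ADC"])]
    cen <- apply_lloq(pred$dv_obs, pred$entity, model$lloq, context_adc = adc_at)

    dose_rows <- tibble::tibble(
      id = id, cohort = ch$cohort, time = reg$events$time, evid = 1L,
      amt = reg$events$amount_nmol,
      rate = reg$events$amount_nmol / reg$events$duration_day,
      mdv = 1L, entity = "DOSE", dv = NA_real_, blq = FALSE,
      lloq = NA_real_, units = "nmol", bsa = bsa
    )
    ob <- tibble::tibble(
      id = id, cohort = ch$cohort, time = pred$time, evid = 0L,
      amt = NA_real_, rate = NA_real_, mdv = ifelse(cen$blq, 1L, 0L),
      entity = pred$entity, dv = cen$value, blq = cen$blq, lloq = cen$lloq,
      units = unname(units[pred$entity]), bsa = bsa
    )
    obs_rows[[id]] <- dplyr::arrange(dplyr::bind_rows(dose_rows, ob),
                                     .data$time, .data$evid, .data$entity)
    subj_rows[[id]] <- ind
  }

  structure(
    list(observations = dplyr::bind_rows(obs_rows),
         subjects = dplyr::bind_rows(subj_rows),
         design = design, seed = seed),
    class = "adc_trial"
  )
}

#' @export
print.adc_trial <- function(x, ...) {
  obs <- x$observations[x$observations$evid == 0, ]
  cat(sprintf("<adc_trial> %d subjects, %d observations (%d BLQ), %d DAR-subset subjects\n",
              length(unique(x$observations$id)), nrow(obs), sum(obs$blq),
              sum(x$subjects$dar_subset)))
  invisible(x)
}

#' BLQ share per entity of a generated trial
#'
#' @param trial an `adc_trial` (or its observation table).
#' @return A tibble `entity`, `n`, `n_blq`, `blq_frac`.
#' @export
blq_summary <- function(trial) {
  obs <- if (inherits(trial, "adc_trial")) trial$observations else trial
  obs <- obs[obs$evid == 0, ]
  dplyr::summarise(dplyr::group_by(obs, .data$entity),
                   n = dplyr::n(), n_blq = sum(.data$blq),
                   blq_frac = mean(.data$blq), .groups = "drop")
}
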