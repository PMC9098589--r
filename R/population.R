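#' Sample individual parameter sets
#'
#' Draws `n` individuals from the population model: every parameter with a
#' non-zero omega is multiplied by `exp(eta)`, `eta ~ N(0, omega^2)`. A
#' single shared `eta_kdec` multiplies all eight deconjugation rates. The
#' administered dose fractions DAR0..DAR7 are perturbed log-normally and the
#' DAR8 fraction is back-calculated as one minus their sum, so every
#' sampled fraction vector sums to one; draws for which the closure would be
#' negative are rejected and redrawn (the count is reported in the
#' `resamples` attribute).
#'
#' Randomness comes from the session RNG; callers seed with `set.seed()`
#' (the trial generator does this per subject for reproducibility).
#'
#' @param params typical values, an [adc_params()] object.
#' @param iiv an [adc_iiv()] object.
#' @param n number of individuals.
#' @return A tibble with one row per individual: `id`, the individual
#'   structural parameters, the fractions `f_DAR0..f_DAR8`, and the sampled
#'   random effects as `eta_*` columns.
#' @examples
#' set.seed(1)
#' ind <- sample_individual(adc_params(), adc_iiv(), n = 3)
#' ind$cl_adc
#' @export
sample_individual <- function(params, iiv, n = 1) {
  stopifnot(inherits(params, "adc_params"), inherits(iiv, "adc_iiv"))
  om <- iiv$omega
  draw_one <- function(id) {
    eta <- stats::rnorm(length(om), 0, om)
    names(eta) <- names(om)
    # fractions: perturb DAR0..DAR7, DAR8 absorbs closure
    resamples <- 0L
    repeat {
      eta_f <- stats::rnorm(8, 0, iiv$f)
      f07 <- params$f[1:8] * exp(eta_f)
      f8 <- 1 - sum(f07)
      if (f8 >= 0 && all(f07 <= 1)) break
      resamples <- resamples + 1L
      if (resamples > 1000L) stop("fraction renormalization infeasible", call. = FALSE)
    }
    f <- c(f07, f8)
    names(f) <- paste0("DAR", 0:8)
    out <- tibble::tibble(
      id = id,
      cl_adc = params$cl_adc * exp(eta[["cl_adc"]]),
      v_c = params$v_c * exp(eta[["v_c"]]),
      q = params$q * exp(eta[["q"]]),
      v_p = params$v_p * exp(eta[["v_p"]]),
      cl_nab = params$cl_nab * exp(eta[["cl_nab"]]),
      cl_dm4 = params$cl_dm4 * exp(eta[["cl_dm4"]]),
      cl_medm4 = params$cl_medm4 * exp(eta[["cl_medm4"]]),
      fr_medm4 = min(1, params$fr_medm4 * exp(eta[["fr_medm4"]]))
    )
    for (i in 1:6) {
      out[[paste0("kdec", i)]] <- params$kdec[[i]] * exp(eta[["kdec"]])
    }
    for (i in 0:8) out[[paste0("f_DAR", i)]] <- f[[i + 1]]
    for (p in names(eta)) out[[paste0("eta_", p)]] <- eta[[p]]
    attr(out, "resamples") <- resamples
    out
  }
  rows <- lapply(seq_len(n), draw_one)
  res <- dplyr::bind_rows(rows)
  attr(res, "resamples") <- sum(vapply(rows, function(r)
    attr(r, "resamples"), integer(1)))
  res
}

#' Rebuild an `adc_params` object from one sampled-individual row
#'
#' @param params the typical-value [adc_params()] (source of tied values).
#' @param row a one-row data frame as returned by [sample_individual()].
#' @return An `adc_params` object for that individual.
#' @export
params_from_row <- function(params, row) {
  stopifnot(nrow(row) == 1)
  adc_params(
    f_nab = row$f_DAR0, f_dar1 = row$f_DAR1, f_dar2 = row$f_DAR2,
    f_dar3 = row$f_DAR3, f_dar4 = row$f_DAR4, f_dar5 = row$f_DAR5,
    f_dar6 = row$f_DAR6, f_dar7 = row$f_DAR7, f_dar8 = row$f_DAR8,
    cl_adc = row$cl_adc, v_c = row$v_c, q = row$q, v_p = row$v_p,
    kdec1 = row$kdec1, kdec2 = row$kdec2, kdec3 = row$kdec3,
    kdec4 = row$kdec4, kdec5 = row$kdec5, kdec6 = row$kdec6,
    cl_nab = row$cl_nab, cl_dm4 = row$cl_dm4, cl_medm4 = row$cl_medm4,
    fr_medm4 = row$fr_medm4, v_dm4 = params$v_dm4, v_medm4 = params$v_medm4
  )
}

#' Residual-error standard deviation for a predicted value
#'
#' Entity-specific residual model on the assay scale: combined
#' (`a + b * f`) for ADC, proportional for DM4, MeDM4 and NAB, additive for
#' the average DAR and the DAR relative proportions.
#'
#' @param pred predicted value(s) on the observation scale (ug/mL for ADC
#'   and NAB, ng/mL for DM4 and MeDM4, natural units for DAR streams).
#' @param entity entity code(s): `"ADC"`, `"NAB"`, `"DM4"`, `"MeDM4"`,
#'   `"DARavg"`, `"PROP_NAB"`, `"PROP_DAR1"`..`"PROP_DAR7"` (recycled).
#' @param res an [adc_residual()] object.
#' @return Standard deviation(s), same length as `pred`.
#' @export
residual_sd <- function(pred, entity, res) {
  stopifnot(inherits(res, "adc_residual"))
  n <- max(length(pred), length(entity))
  pred <- rep_len(pred, n)
  entity <- rep_len(entity, n)
  sd <- numeric(n)
  for (e in unique(entity)) {
    k <- entity == e
    sd[k] <- switch(e,
      ADC = res$a_adc + res$b_adc * pred[k],
      NAB = res$b_nab * pred[k],
      DM4 = res$b_dm4 * pred[k],
      MeDM4 = res$b_medm4 * pred[k],
      DARavg = res$a_dar_average,
      {
        if (!grepl("^PROP_", e)) stop("unknown entity: ", e, call. = FALSE)
        key <- sub("PROP_", "", e)
        if (!key %in% names(res$a_prop)) stop("unknown entity: ", e, call. = FALSE)
        res$a_prop[[key]]
      })
  }
  sd
}

#' Draw observations under the residual-error model
#'
#' `Obs = f + (a + b * f) * sigma`, `sigma ~ N(0, 1)`. Values may be
#' negative before censoring; censoring is applied separately by
#' [apply_lloq()].
#'
#' @inheritParams residual_sd
#' @return Observed value(s).
#' @export
residual_observe <- function(pred, entity, res) {
  sd <- residual_sd(pred, entity, res)
  pred + stats::rnorm(length(sd), 0, sd)
}

#' Apply lower-limit-of-quantification censoring
#'
#' Flags observations below their assay limit as BLQ and attaches the limit.
#' The NAB limit is concentration-dependent: samples are diluted until the
#' co-measured ADC concentration falls below the dilution threshold, and the
#' base limit is inflated by the dilution factor
#' `DF = ceiling(C_ADC / threshold)` up to the assay cap, reproducing the
#' observed 1--9.60 ug/mL range.
#'
#' @param obs observed value(s) on the assay scale.
#' @param entity entity code(s), recycled.
#' @param rule an [adc_lloq()] object.
#' @param context_adc co-measured ADC concentration(s) (ug/mL), used only
#'   for the NAB limit; recycled.
#' @return A tibble with columns `value` (NA when censored), `blq` and
#'   `lloq` (NA for streams without a quantification limit).
#' @examples
#' apply_lloq(c(0.4, 5), c("ADC", "NAB"), adc_lloq(), context_adc = c(0.4, 100))
#' @export
apply_lloq <- function(obs, entity, rule = adc_lloq(), context_adc = NA_real_) {
  stopifnot(inherits(rule, "adc_lloq"))
  n <- max(length(obs), length(entity))
  obs <- rep_len(obs, n)
  entity <- rep_len(entity, n)
  context_adc <- rep_len(context_adc, n)
  lloq <- rep(NA_real_, n)
  lloq[entity == "ADC"] <- rule$adc
  lloq[entity == "DM4"] <- rule$dm4
  lloq[entity == "MeDM4"] <- rule$medm4
  is_nab <- entity == "NAB"
  if (any(is_nab)) {
    df <- pmax(1, ceiling(ifelse(is.na(context_adc[is_nab]), 0,
                                 context_adc[is_nab]) /
                            rule$nab_dilution_threshold))
    lloq[is_nab] <- pmin(rule$nab_base * df, rule$nab_lloq_max)
  }
  blq <- !is.na(lloq) & obs < lloq
  tibble::tibble(value = ifelse(blq, NA_real_, obs), blq = blq, lloq = lloq)
}

#' Convert between assay mass units and molar concentration
#'
#' ADC and NAB assays report ug/mL, the payload assays ng/mL; the model works
#' in uM. Each entity is converted with its own molecular weight
#' (ADC 150,000; NAB 144,522; DM4 780; MeDM4 794 g/mol).
#'
#' @param value value(s) to convert.
#' @param entity `"ADC"`, `"NAB"`, `"DM4"` or `"MeDM4"` (recycled).
#' @param direction `"mass_to_molar"` (assay scale to uM) or
#'   `"molar_to_mass"`.
#' @return Converted value(s).
#' @examples
#' convert_units(150, "ADC", "mass_to_molar")   # 1 uM
#' convert_units(0.78, "DM4", "mass_to_molar")  # 0.001 uM
#' @export
convert_units <- function(value, entity,
                          direction = c("mass_to_molar", "molar_to_mass")) {
  direction <- match.arg(direction)
  mw <- c(ADC = 150000, NAB = 144522, DM4 = 780, MeDM4 = 794)
  # ug/mL -> uM is 1000/MW; ng/mL -> uM is 1/MW
  fac <- c(ADC = 1000, NAB = 1000, DM4 = 1, MeDM4 = 1) / mw
  n <- max(length(value), length(entity))
  value <- rep_len(value, n)
  entity <- rep_len(entity, n)
  if (!all(entity %in% names(fac))) {
    stop("unknown entity in unit conversion", call. = FALSE)
  }
  f <- unname(fac[entity])
  if (direction == "mass_to_molar") value * f else value / f
}
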