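#' @noRd
#' Split an observation table into per-subject structures used by the
#' likelihood, the fitting algorithm and the diagnostics.
prep_subjects <- function(data) {
  if (inherits(data, "adc_trial")) data <- data$observations
  data <- tibble::as_tibble(data)
  ids <- unique(data$id)
  lapply(ids, function(i) {
    d <- data[data$id == i, ]
    dose <- d[d$evid == 1, ]
    if (nrow(dose) == 0) {
      events <- tibble::tibble(time = numeric(0), amount_nmol = numeric(0),
                               duration_day = numeric(0))
    } else {
      events <- tibble::tibble(time = dose$time, amount_nmol = dose$amt,
                               duration_day = dose$amt / dose$rate)
    }
    obs <- d[d$evid == 0, ]
    list(id = i, events = events,
         obs = tibble::tibble(time = obs$time, entity = obs$entity,
                              dv = obs$dv, blq = obs$blq, lloq = obs$lloq))
  })
}

#' @noRd
#' Model prediction for every observation row of one prepared subject.
subject_pred <- function(params, sub) {
  pr <- predict_entities(params, sub$events, sub$obs$time,
                         entities = unique(sub$obs$entity))
  pr$pred[match(paste(sub$obs$time, sub$obs$entity),
                paste(pr$time, pr$entity))]
}

#' @noRd
#' Gaussian/M3 log-likelihood given predictions and residual spec.
loglik_from_pred <- function(pred, obs, res) {
  sd <- pmax(residual_sd(pred, obs$entity, res), 1e-10)
  ll <- numeric(nrow(obs))
  nb <- !obs$blq
  ll[nb] <- stats::dnorm(obs$dv[nb], pred[nb], sd[nb], log = TRUE)
  if (any(obs$blq)) {
    ll[obs$blq] <- stats::pnorm(obs$lloq[obs$blq], pred[obs$blq],
                                sd[obs$blq], log.p = TRUE)
  }
  # DAR streams can be undefined (NA prediction) pre-dose; such rows are
  # not generated, but guard against them
  ll[is.na(ll)] <- -1e10
  sum(ll)
}

#' Individual-data log-likelihood under the censored (M3) observation model
#'
#' Non-BLQ rows contribute the normal density of the entity's residual
#' model; BLQ rows contribute the normal CDF at their LLOQ (the M3 method),
#' so censored records inform the fit without an imputed value.
#'
#' @param params individual [adc_params()].
#' @param data observation table rows for one subject (dose events
#'   included; an `adc_trial` is also accepted and must contain a single
#'   subject).
#' @param res an [adc_residual()] object.
#' @return Log-likelihood (scalar).
#' @export
individual_loglik <- function(params, data, res = adc_residual()) {
  subs <- prep_subjects(data)
  if (length(subs) != 1) {
    stop("individual_loglik expects a single subject; got ", length(subs),
         call. = FALSE)
  }
  sub <- subs[[1]]
  loglik_from_pred(subject_pred(params, sub), sub$obs, res)
}

#' @noRd
#' Build individual parameters from log-scale individual values phi for the
#' estimated names, everything else at `base`. Lean hot-path version of
#' [update_params()]: exp(phi) is always positive so the constructor
#' validation is skipped; the kdec7 = kdec8 = kdec6 tie and the [0, 1]
#' bound on fr_medm4 are re-applied.
params_from_phi <- function(base, phi, map = NULL) {
  v <- exp(phi)
  if (is.null(map)) map <- phi_map(names(phi))
  if (length(map$kidx)) {
    base$kdec[map$kidx] <- v[map$kd]
    base$kdec[7:8] <- base$kdec[[6]]
  }
  for (k in map$other) base[[map$nm[k]]] <- v[[k]]
  if (base$fr_medm4 > 1) base$fr_medm4 <- 1
  base
}

#' @noRd
#' Precomputed name mapping for the hot-path parameter constructor.
phi_map <- function(nm) {
  kd <- grepl("^kdec", nm)
  list(nm = nm, kd = kd,
       kidx = as.integer(sub("kdec", "", nm[kd])),
       other = which(!kd))
}
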