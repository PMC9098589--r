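#' Empirical Bayes (MAP) individual random effects
#'
#' Maximizes, per subject, the posterior of the individual log-parameters
#' `phi` under the population model: the M3 individual likelihood plus the
#' log-normal prior `phi ~ N(log theta, omega^2)`. Gradient-free
#' (Nelder-Mead) optimization started at the prior mode; subjects with no
#' observations return `eta = 0`.
#'
#' @param data observation table (any form accepted by [fit_saem()]).
#' @param model an [adc_model()] (e.g. [fitted_model()] of a fit).
#' @param estimate parameters carrying random effects.
#' @param maxit Nelder-Mead iteration budget per subject.
#' @return A tibble: `id`, one `eta_*` column per parameter, and the
#'   attained posterior log-density `lpost`.
#' @export
empirical_bayes <- function(data, model, estimate = default_estimated(),
                            maxit = 500) {
  stopifnot(inherits(model, "adc_model"))
  subs <- prep_fast(prep_subjects(data))
  base <- model$params
  lt <- log(theta_from_params(base, estimate))
  om <- pmax(omega_init(model$iiv, estimate), 1e-6)
  P <- length(estimate)
  pmap <- phi_map(estimate)

  one <- function(sub) {
    if (nrow(sub$obs) == 0) {
      return(c(rep(0, P), sum(stats::dnorm(rep(0, P), 0, om, log = TRUE))))
    }
    neg <- function(eta) {
      sl <- safe_loglik(params_from_phi(base, lt + eta, pmap), sub, model$residual)
      -(sl$ll + sum(stats::dnorm(eta, 0, om, log = TRUE)))
    }
    if (P == 1) {
      opt <- stats::optim(0, neg, method = "Brent", lower = -8 * om,
                          upper = 8 * om)
    } else {
      opt <- stats::optim(rep(0, P), neg, method = "Nelder-Mead",
                          control = list(maxit = maxit))
    }
    c(opt$par, -opt$value)
  }
  out <- t(vapply(subs, one, numeric(P + 1)))
  res <- tibble::tibble(id = unlist(lapply(subs, `[[`, "id")))
  for (i in seq_len(P)) res[[paste0("eta_", estimate[i])]] <- out[, i]
  res$lpost <- out[, P + 1]
  res
}

#' Importance-sampling marginal log-likelihood, OF and BIC
#'
#' Estimates each subject's marginal likelihood by importance sampling
#' around the empirical-Bayes mode (proposal: normal centred at the mode
#' with the prior standard deviations), then reports the objective function
#' `OF = -2 * sum(log Lhat)` and `BIC = OF + d * log(N)` with `N` the
#' number of subjects and `d` the number of population parameters
#' (`n_params`; by default the estimated fixed effects plus their omegas
#' plus the residual terms of the streams present).
#'
#' @inheritParams empirical_bayes
#' @param mc_size Monte-Carlo samples per subject.
#' @param seed RNG seed.
#' @param n_params parameter count used in the BIC penalty; `NULL` for the
#'   default described above.
#' @param eb optional precomputed [empirical_bayes()] table.
#' @return A list: `ofv`, `bic`, `loglik`, `n_params`, `n_subjects`, and
#'   the per-subject log-likelihoods `by_subject`.
#' @export
population_loglik <- function(data, model, estimate = default_estimated(),
                              mc_size = 1000, seed = 1, n_params = NULL,
                              eb = NULL) {
  stopifnot(inherits(model, "adc_model"))
  subs <- prep_fast(prep_subjects(data))
  if (is.null(eb)) eb <- empirical_bayes(data, model, estimate)
  set.seed(seed %% .Machine$integer.max)
  base <- model$params
  lt <- log(theta_from_params(base, estimate))
  om <- pmax(omega_init(model$iiv, estimate), 1e-6)
  P <- length(estimate)
  pmap <- phi_map(estimate)
  eta_cols <- paste0("eta_", estimate)

  ll_j <- vapply(seq_along(subs), function(j) {
    sub <- subs[[j]]
    mode <- as.numeric(eb[eb$id == sub$id, eta_cols])
    lw <- vapply(seq_len(mc_size), function(m) {
      eta <- mode + stats::rnorm(P, 0, om)
      sl <- safe_loglik(params_from_phi(base, lt + eta, pmap), sub, model$residual)
      sl$ll + sum(stats::dnorm(eta, 0, om, log = TRUE)) -
        sum(stats::dnorm(eta, mode, om, log = TRUE))
    }, numeric(1))
    mx <- max(lw)
    if (!is.finite(mx)) return(-Inf)
    mx + log(mean(exp(lw - mx)))
  }, numeric(1))

  if (is.null(n_params)) {
    ent <- unique(unlist(lapply(subs, function(s) names(s$rows))))
    n_res <- sum(c("ADC" %in% ent) * 2, "NAB" %in% ent, "DM4" %in% ent,
                 "MeDM4" %in% ent, "DARavg" %in% ent)
    n_params <- 2 * P + n_res
  }
  ofv <- -2 * sum(ll_j)
  list(ofv = ofv, bic = ofv + n_params * log(length(subs)),
       loglik = sum(ll_j), n_params = n_params, n_subjects = length(subs),
       by_subject = tibble::tibble(id = unlist(lapply(subs, `[[`, "id")),
                                   loglik = ll_j))
}
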