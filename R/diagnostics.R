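#' @noRd
#' Lean individual-parameter draw for simulation replicates: same
#' distribution as [sample_individual()] (shared kdec eta, DAR8
#' back-calculated fraction closure) without the bookkeeping.
sample_params_fast <- function(params, iiv) {
  om <- iiv$omega
  eta <- stats::rnorm(9, 0, om)
  p <- params
  p$cl_adc <- p$cl_adc * exp(eta[[1]])
  p$v_c <- p$v_c * exp(eta[[2]])
  p$q <- p$q * exp(eta[[3]])
  p$v_p <- p$v_p * exp(eta[[4]])
  p$kdec <- p$kdec * exp(eta[[5]])
  p$cl_nab <- p$cl_nab * exp(eta[[6]])
  p$cl_dm4 <- p$cl_dm4 * exp(eta[[7]])
  p$cl_medm4 <- p$cl_medm4 * exp(eta[[8]])
  p$fr_medm4 <- min(1, p$fr_medm4 * exp(eta[[9]]))
  repeat {
    f07 <- params$f[1:8] * exp(stats::rnorm(8, 0, iiv$f))
    f8 <- 1 - sum(f07)
    if (f8 >= 0 && all(f07 <= 1)) break
  }
  p$f <- c(f07, DAR8 = unname(f8))
  p
}

#' @noRd
#' Residual-error draw aligned with the per-entity row index of a
#' prepared subject (hot path of the replicate simulator).
residual_observe_fast <- function(pred, sub, res) {
  sd <- fast_sd(pred, sub, res)
  pred + stats::rnorm(length(sd), 0, sd)
}

#' @noRd
#' Population simulation replicates at the subjects' own designs.
#' Returns, per subject, an n_obs x nsim matrix of simulated observations
#' (IIV + residual error, no censoring), plus the typical-parameter
#' prediction for every observation row.
simulate_population <- function(subs, model, nsim, seed,
                                include_residual = TRUE) {
  set.seed(seed %% .Machine$integer.max)
  sims <- vector("list", length(subs))
  pred_typ <- vector("list", length(subs))
  for (j in seq_along(subs)) {
    sub <- subs[[j]]
    pred_typ[[j]] <- fast_pred(model$params, sub)
    S <- matrix(NA_real_, nrow(sub$obs), nsim)
    for (r in seq_len(nsim)) {
      p_i <- sample_params_fast(model$params, model$iiv)
      f <- fast_pred(p_i, sub)
      S[, r] <- if (include_residual) {
        residual_observe_fast(f, sub, model$residual)
      } else f
    }
    sims[[j]] <- S
  }
  list(sims = sims, pred_typical = pred_typ)
}

#' Population and individual weighted residuals
#'
#' `iWRES = (obs - ipred) / sd(ipred)` with the individual prediction from
#' the empirical-Bayes random effects. `PWRES` decorrelates the population
#' residual per subject with the mean and covariance of `nsim` population
#' simulation replicates: `PWRES = L^-1 (obs - mean)` with `LL' = cov`.
#' BLQ rows get `NA` residuals.
#'
#' @param data observation table.
#' @param model an [adc_model()] (true or fitted).
#' @param nsim simulation replicates for the PWRES mean/covariance.
#' @param seed RNG seed.
#' @param estimate parameters carrying random effects (for the EB step).
#' @param eb optional precomputed [empirical_bayes()] table.
#' @return A tibble: `id`, `time`, `entity`, `dv`, `blq`, `pred`
#'   (simulation mean), `ipred`, `iwres`, `pwres`.
#' @export
pwres_iwres <- function(data, model, nsim = 500, seed = 1,
                        estimate = default_estimated(), eb = NULL) {
  stopifnot(inherits(model, "adc_model"))
  subs <- prep_fast(prep_subjects(data))
  if (is.null(eb)) eb <- empirical_bayes(data, model, estimate)
  sp <- simulate_population(subs, model, nsim, seed)
  base <- model$params
  lt <- log(theta_from_params(base, estimate))
  pmap <- phi_map(estimate)
  eta_cols <- paste0("eta_", estimate)

  out <- vector("list", length(subs))
  for (j in seq_along(subs)) {
    sub <- subs[[j]]
    eta <- as.numeric(eb[eb$id == sub$id, eta_cols])
    ipred <- fast_pred(params_from_phi(base, lt + eta, pmap), sub)
    isd <- pmax(residual_sd(ipred, sub$obs$entity, model$residual), 1e-10)
    iwres <- (sub$obs$dv - ipred) / isd

    S <- sp$sims[[j]]
    keep <- !sub$obs$blq
    pwres <- rep(NA_real_, nrow(sub$obs))
    if (sum(keep) >= 1) {
      Sk <- S[keep, , drop = FALSE]
      m <- rowMeans(Sk)
      V <- stats::cov(t(Sk))
      V <- V + diag(1e-8 * mean(diag(as.matrix(V))) + 1e-12, nrow(Sk))
      L <- t(chol(V))
      pwres[keep] <- as.numeric(forwardsolve(L, sub$obs$dv[keep] - m))
    }
    out[[j]] <- tibble::tibble(
      id = sub$id, time = sub$obs$time, entity = sub$obs$entity,
      dv = sub$obs$dv, blq = sub$obs$blq, pred = rowMeans(S),
      ipred = ipred, iwres = ifelse(sub$obs$blq, NA_real_, iwres),
      pwres = pwres
    )
  }
  dplyr::bind_rows(out)
}

#' Goodness-of-fit report
#'
#' Bundles the standard qualification displays: observed versus population
#' and individual predictions, and weighted residuals versus time and
#' versus prediction, per entity. Optionally writes the residual table and
#' per-entity summaries as CSV.
#'
#' @inheritParams pwres_iwres
#' @param path optional directory for CSV output.
#' @return A list with `residuals` (the [pwres_iwres()] table), `summary`
#'   (per-entity residual moments) and `plots` (named ggplot objects).
#' @export
gof_report <- function(data, model, nsim = 500, seed = 1,
                       estimate = default_estimated(), eb = NULL,
                       path = NULL) {
  obs <- if (inherits(data, "adc_trial")) data$observations else data
  if (nrow(obs[obs$evid == 0, ]) == 0) stop("empty dataset", call. = FALSE)
  rt <- pwres_iwres(data, model, nsim = nsim, seed = seed,
                    estimate = estimate, eb = eb)
  smry <- dplyr::summarise(
    dplyr::group_by(rt[!rt$blq, ], .data$entity),
    n = dplyr::n(),
    mean_iwres = mean(.data$iwres), sd_iwres = stats::sd(.data$iwres),
    mean_pwres = mean(.data$pwres), sd_pwres = stats::sd(.data$pwres),
    .groups = "drop")
  ok <- rt[!rt$blq, ]
  plots <- list(
    obs_vs_pred = ggplot2::ggplot(ok, ggplot2::aes(.data$pred, .data$dv)) +
      ggplot2::geom_point(alpha = 0.3) +
      ggplot2::geom_abline(linetype = 2) +
      ggplot2::facet_wrap(~entity, scales = "free") +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "population prediction", y = "observation"),
    obs_vs_ipred = ggplot2::ggplot(ok, ggplot2::aes(.data$ipred, .data$dv)) +
      ggplot2::geom_point(alpha = 0.3) +
      ggplot2::geom_abline(linetype = 2) +
      ggplot2::facet_wrap(~entity, scales = "free") +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "individual prediction", y = "observation"),
    iwres_vs_time = ggplot2::ggplot(ok, ggplot2::aes(.data$time, .data$iwres)) +
      ggplot2::geom_point(alpha = 0.3) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::facet_wrap(~entity) +
      ggplot2::labs(x = "time (days)", y = "iWRES"),
    pwres_vs_time = ggplot2::ggplot(ok, ggplot2::aes(.data$time, .data$pwres)) +
      ggplot2::geom_point(alpha = 0.3) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::facet_wrap(~entity) +
      ggplot2::labs(x = "time (days)", y = "PWRES")
  )
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(rt, file.path(path, "residuals.csv"))
    readr::write_csv(smry, file.path(path, "residual_summary.csv"))
  }
  list(residuals = rt, summary = smry, plots = plots)
}
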