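#' Normalized prediction distribution errors
#'
#' For each subject, simulates `nsim` replicate observation vectors under
#' the population model, decorrelates both the observed and the simulated
#' vectors with the empirical mean and Cholesky factor of the replicates,
#' computes the prediction discrepancies as ranks of the decorrelated
#' observation within its decorrelated replicates (ties broken by
#' half-rank), clips them to `(1/(2 nsim), 1 - 1/(2 nsim))` and maps them
#' through the inverse normal CDF. Under the true model the NPDE are
#' standard normal. BLQ rows are excluded.
#'
#' @param data observation table.
#' @param model an [adc_model()].
#' @param nsim replicate datasets.
#' @param seed RNG seed.
#' @param entities entity streams included (default the four
#'   concentration streams present).
#' @return A tibble of class `adc_npde`: `id`, `time`, `entity`, `dv`,
#'   `npde`; the summary (mean, variance, t-test and normality test) is in
#'   `attr(, "summary")` and via [npde_summary()].
#' @export
npde <- function(data, model, nsim = 500, seed = 1,
                 entities = c("ADC", "NAB", "DM4", "MeDM4")) {
  stopifnot(inherits(model, "adc_model"))
  obs <- if (inherits(data, "adc_trial")) data$observations else data
  dat <- obs[obs$evid == 1 | (obs$entity %in% entities & !obs$blq), ]
  subs <- prep_fast(prep_subjects(dat))
  subs <- Filter(function(s) nrow(s$obs) > 0, subs)
  if (!length(subs)) stop("no quantifiable observations", call. = FALSE)
  sp <- simulate_population(subs, model, nsim, seed)

  out <- vector("list", length(subs))
  for (j in seq_along(subs)) {
    sub <- subs[[j]]
    y <- sub$obs$dv
    S <- sp$sims[[j]]
    m <- rowMeans(S)
    V <- stats::cov(t(S))
    V <- V + diag(1e-8 * mean(diag(as.matrix(V))) + 1e-12, length(y))
    L <- t(chol(V))
    ystar <- as.numeric(forwardsolve(L, y - m))
    Sstar <- forwardsolve(L, S - m)
    pd <- vapply(seq_along(y), function(i) {
      (sum(Sstar[i, ] < ystar[i]) + 0.5 * sum(Sstar[i, ] == ystar[i])) / nsim
    }, numeric(1))
    pd <- pmin(pmax(pd, 1 / (2 * nsim)), 1 - 1 / (2 * nsim))
    out[[j]] <- tibble::tibble(id = sub$id, time = sub$obs$time,
                               entity = sub$obs$entity, dv = y,
                               npde = stats::qnorm(pd))
  }
  res <- dplyr::bind_rows(out)
  v <- res$npde
  sh <- stats::shapiro.test(if (length(v) > 5000) {
    set.seed(seed); sample(v, 5000)
  } else v)
  smry <- tibble::tibble(
    n = length(v), mean = mean(v), variance = stats::var(v),
    t_pvalue = stats::t.test(v)$p.value,
    shapiro_w = unname(sh$statistic), shapiro_pvalue = sh$p.value
  )
  structure(res, class = c("adc_npde", class(res)), summary = smry,
            nsim = nsim)
}

#' Summary statistics of an NPDE table
#'
#' @param x an `adc_npde` object.
#' @return A one-row tibble: `n`, `mean`, `variance`, t-test p-value for
#'   mean zero, Shapiro-Wilk statistic and p-value.
#' @export
npde_summary <- function(x) {
  stopifnot(inherits(x, "adc_npde"))
  attr(x, "summary")
}

#' @export
autoplot.adc_npde <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$npde)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_hline(yintercept = c(-1.96, 0, 1.96), linetype = c(3, 2, 3)) +
    ggplot2::facet_wrap(~entity) +
    ggplot2::labs(x = "time (days)", y = "NPDE")
}
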