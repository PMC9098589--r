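#' Tidy a SAEM fit
#'
#' @param x an `adc_fit`.
#' @param ... unused.
#' @return A tibble with one row per estimated quantity: `term`, `type`
#'   (`"theta"`, `"omega"` or `"residual"`) and `estimate`.
#' @export
tidy.adc_fit <- function(x, ...) {
  res <- x$residual
  res_rows <- tibble::tibble(
    term = c("a_adc", "b_adc", "b_dm4", "b_medm4", "b_nab"),
    type = "residual",
    estimate = c(res$a_adc, res$b_adc, res$b_dm4, res$b_medm4, res$b_nab)
  )
  dplyr::bind_rows(
    tibble::tibble(term = x$estimate, type = "theta",
                   estimate = unname(x$theta)),
    tibble::tibble(term = paste0("omega_", x$estimate), type = "omega",
                   estimate = unname(x$omega)),
    res_rows
  )
}

#' Glance at a SAEM fit
#'
#' @param x an `adc_fit`.
#' @param ... unused.
#' @return One-row tibble: subject and observation counts, iteration
#'   counts, convergence flag.
#' @export
glance.adc_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects, n_obs = x$n_obs,
    n_estimated = length(x$estimate),
    n_explore = x$settings$n_explore, n_smooth = x$settings$n_smooth,
    converged = x$converged
  )
}

#' Parameter-trajectory plot of a SAEM fit
#'
#' @param object an `adc_fit`.
#' @param ... unused.
#' @return A ggplot of the fixed-effect trajectories over SAEM iterations
#'   (vertical line at the exploration/smoothing switch).
#' @export
autoplot.adc_fit <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trajectories, -"iteration",
                            names_to = "parameter", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$settings$n_explore,
                        linetype = 3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "SAEM iteration", y = "estimate")
}

#' Concentration-profile plot of a simulation
#'
#' @param object an `adc_sim` from [simulate_profile()].
#' @param entities which entities to draw.
#' @param log_y logarithmic concentration axis.
#' @param ... unused.
#' @return A ggplot of entity concentrations over time.
#' @export
autoplot.adc_sim <- function(object, entities = c("ADC", "NAB", "DM4", "MeDM4"),
                             log_y = TRUE, ...) {
  cols <- vapply(entities, function(e) switch(e,
    ADC = "C_ADC", NAB = "C_NAB", TAB = "C_TAB", DM4 = "C_DM4",
    MeDM4 = "C_MeDM4", paste0("C_", e)), character(1))
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("time", unname(cols))],
    -"time", names_to = "entity", values_to = "conc")
  df$entity <- names(cols)[match(df$entity, cols)]
  p <- ggplot2::ggplot(df[df$conc > 0, ],
                       ggplot2::aes(.data$time, .data$conc,
                                    colour = .data$entity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "concentration (uM)",
                  colour = NULL)
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Average-DAR profile plot
#'
#' @param sim an `adc_sim`.
#' @return A ggplot of the average DAR over time.
#' @export
plot_dar_average <- function(sim) {
  df <- tibble::as_tibble(sim)[c("time", "dar_average")]
  ggplot2::ggplot(df[!is.na(df$dar_average), ],
                  ggplot2::aes(.data$time, .data$dar_average)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "average DAR") +
    ggplot2::ylim(0, 8)
}
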