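#' Intravenous infusion regimen
#'
#' Describes repeated short intravenous infusions: a dose level in mg/m^2
#' (converted to molar amount via the body-surface area and the ADC
#' molecular weight of 150,000 g/mol), the dosing interval (14 days for
#' Q2W, 21 for Q3W), the number of administrations, and the infusion
#' duration. A distinct first-cycle loading dose is supported.
#'
#' @param dose_mg_m2 dose level (mg/m^2) from cycle 2 onwards (and cycle 1
#'   unless `loading_dose_mg_m2` is given).
#' @param interval_days dosing interval in days (one cycle).
#' @param n_cycles number of administrations.
#' @param infusion_hours infusion duration (hours). The study infusion
#'   duration is short relative to every disposition time constant; 1 h is
#'   the package default and all dose-independent outputs are insensitive
#'   to it.
#' @param bsa body-surface area (m^2) used for the mg/m^2 to mg conversion.
#' @param loading_dose_mg_m2 optional different first-administration dose.
#' @param mw_adc molecular weight used for the molar conversion (g/mol).
#' @return An object of class `adc_regimen` carrying a `events` tibble with
#'   columns `time` (days), `amount_nmol` and `duration_day`.
#' @examples
#' adc_regimen(100, interval_days = 14, n_cycles = 4)
#' @export
adc_regimen <- function(dose_mg_m2, interval_days = 14, n_cycles = 1,
                        infusion_hours = 1, bsa = 1.8,
                        loading_dose_mg_m2 = NULL, mw_adc = 150000) {
  stopifnot(is.finite(dose_mg_m2), dose_mg_m2 >= 0,
            is.finite(interval_days), interval_days > 0,
            is.finite(infusion_hours), infusion_hours > 0,
            is.finite(bsa), bsa > 0, n_cycles >= 1)
  doses <- rep(dose_mg_m2, n_cycles)
  if (!is.null(loading_dose_mg_m2)) doses[1] <- loading_dose_mg_m2
  events <- tibble::tibble(
    time = (seq_len(n_cycles) - 1) * interval_days,
    amount_nmol = doses * bsa * 1e6 / mw_adc,
    duration_day = infusion_hours / 24
  )
  structure(
    list(dose_mg_m2 = dose_mg_m2, interval_days = interval_days,
         n_cycles = n_cycles, infusion_hours = infusion_hours, bsa = bsa,
         loading_dose_mg_m2 = loading_dose_mg_m2, mw_adc = mw_adc,
         events = events),
    class = "adc_regimen"
  )
}

#' @export
print.adc_regimen <- function(x, ...) {
  cat(sprintf("<adc_regimen> %g mg/m^2 every %g days x %d (%.2g h infusion, BSA %.2g m^2)\n",
              x$dose_mg_m2, x$interval_days, x$n_cycles, x$infusion_hours, x$bsa))
  if (!is.null(x$loading_dose_mg_m2)) {
    cat(sprintf("  loading dose %g mg/m^2 at cycle 1\n", x$loading_dose_mg_m2))
  }
  invisible(x)
}
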