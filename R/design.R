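#' Virtual first-in-human trial design
#'
#' Describes the cohort structure of the emulated dose-escalation /
#' expansion study: dose level (mg/m^2), regimen (Q2W or Q3W), optional
#' cycle-1 loading dose, and the number of patients per cohort. The default
#' reproduces the study layout: a Q2W escalation arm (5--150 mg/m^2, n=31),
#' a Q2W arm with a cycle-1 loading dose followed by 100 mg/m^2 (n=28), a
#' Q3W escalation arm (n=15), and a 100 mg/m^2 Q2W expansion arm (n=180);
#' 254 patients in total, with the DAR streams measured in a subset of 13.
#'
#' Sampling is rich at cycles 1 and 4 and trough-only elsewhere; the number
#' of treated cycles per patient is drawn from a geometric-like distribution
#' with median 4 (the observed median treatment duration), truncated to
#' `max_cycles`.
#'
#' @param cohorts a tibble with columns `cohort`, `dose_mg_m2`,
#'   `interval_days`, `n`, `loading_dose_mg_m2` (NA for none). Default is
#'   the study layout described above.
#' @param dar_subset_n number of patients with DAR measurements.
#' @param rich_cycles cycles with full PK profiles.
#' @param median_cycles median of the per-patient cycle-count distribution.
#' @param max_cycles truncation of the cycle-count distribution.
#' @param fixed_cycles if non-NULL, every patient receives exactly this
#'   many cycles (no dropout), as in designed recovery experiments.
#' @param bsa_mean,bsa_sd,bsa_range body-surface-area distribution
#'   (normal, truncated).
#' @param infusion_hours infusion duration (hours).
#' @return An object of class `adc_design`.
#' @examples
#' d <- trial_design()
#' sum(d$cohorts$n)  # 254
#' @export
trial_design <- function(cohorts = default_cohorts(),
                         dar_subset_n = 13,
                         rich_cycles = c(1, 4),
                         median_cycles = 4,
                         max_cycles = 20,
                         fixed_cycles = NULL,
                         bsa_mean = 1.8, bsa_sd = 0.2,
                         bsa_range = c(1.2, 2.4),
                         infusion_hours = 1) {
  cohorts <- tibble::as_tibble(cohorts)
  need <- c("cohort", "dose_mg_m2", "interval_days", "n", "loading_dose_mg_m2")
  if (!all(need %in% names(cohorts))) {
    stop("cohorts must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(cohorts$n < 0)) stop("cohort sizes must be >= 0", call. = FALSE)
  if (dar_subset_n > sum(cohorts$n)) {
    stop("DAR subset larger than the trial", call. = FALSE)
  }
  structure(
    list(cohorts = cohorts, dar_subset_n = dar_subset_n,
         rich_cycles = rich_cycles, median_cycles = median_cycles,
         max_cycles = max_cycles, fixed_cycles = fixed_cycles,
         bsa_mean = bsa_mean, bsa_sd = bsa_sd,
         bsa_range = bsa_range, infusion_hours = infusion_hours),
    class = "adc_design"
  )
}

#' Default cohort table of the emulated study
#'
#' @return A tibble with one row per (cohort, dose level): the Q2W
#'   escalation, Q2W loading-dose escalation, Q3W escalation and 100 mg/m^2
#'   Q2W expansion cohorts, 254 patients in total.
#' @export
default_cohorts <- function() {
  esc_q2w <- tibble::tibble(
    cohort = "escalation_q2w",
    dose_mg_m2 = c(5, 10, 20, 40, 80, 100, 120, 150),
    interval_days = 14,
    n = c(2, 4, 1, 3, 3, 6, 9, 3),
    loading_dose_mg_m2 = NA_real_
  )
  # loading dose at cycle 1, then 100 mg/m2 Q2W
  esc_load <- tibble::tibble(
    cohort = "escalation_q2w_loading",
    dose_mg_m2 = 100,
    interval_days = 14,
    n = c(3, 4, 8, 13),
    loading_dose_mg_m2 = c(120, 135, 150, 170)
  )
  esc_q3w <- tibble::tibble(
    cohort = "escalation_q3w",
    dose_mg_m2 = c(120, 150, 170, 190),
    interval_days = 21,
    n = c(6, 2, 4, 3),
    loading_dose_mg_m2 = NA_real_
  )
  expansion <- tibble::tibble(
    cohort = "expansion_q2w",
    dose_mg_m2 = 100,
    interval_days = 14,
    n = 180,
    loading_dose_mg_m2 = NA_real_
  )
  dplyr::bind_rows(esc_q2w, esc_load, esc_q3w, expansion)
}

#' Observation-time template for one subject
#'
#' Rich cycles get a full profile (end of infusion; 1, 4 and 8 hours after
#' the end of infusion; days 1, 2, 4, 7 and 10; and the pre-dose trough of
#' the next cycle), sparse cycles a trough only. Times are days from the
#' first administration.
#'
#' @param regimen an [adc_regimen()] for this subject.
#' @param rich_cycles which cycles are richly sampled.
#' @return Sorted numeric vector of observation times (days).
#' @examples
#' make_sampling_schedule(adc_regimen(100, 14, 4))
#' @export
make_sampling_schedule <- function(regimen, rich_cycles = c(1, 4)) {
  stopifnot(inherits(regimen, "adc_regimen"))
  dur <- regimen$infusion_hours / 24
  tau <- regimen$interval_days
  rich_offsets <- c(dur, dur + 1 / 24, dur + 4 / 24, dur + 8 / 24,
                    1, 2, 4, 7, 10, tau - 0.05)
  times <- unlist(lapply(seq_len(regimen$n_cycles), function(cy) {
    start <- (cy - 1) * tau
    if (cy %in% rich_cycles) start + rich_offsets else start + tau - 0.05
  }))
  sort(unique(times))
}

#' Rich single-cohort design for parameter-recovery experiments
#'
#' `n` patients at 100 mg/m^2 Q2W for exactly four cycles with rich
#' sampling at cycles 1 and 4 and troughs elsewhere; DAR streams are
#' measured in a 13-patient subset as in the emulated study. Used by the
#' estimation qualification experiments.
#'
#' @param n number of subjects.
#' @param dar_subset_n patients with DAR streams.
#' @return An `adc_design`.
#' @export
recovery_design <- function(n = 100, dar_subset_n = 13) {
  trial_design(
    cohorts = tibble::tibble(cohort = "recovery", dose_mg_m2 = 100,
                             interval_days = 14, n = n,
                             loading_dose_mg_m2 = NA_real_),
    dar_subset_n = dar_subset_n, fixed_cycles = 4
  )
}

#' @noRd
sample_cycle_count <- function(n, median_cycles, max_cycles) {
  # geometric-like dropout tuned so the median is `median_cycles`
  q <- 0.5^(1 / median_cycles)
  k <- 1 + stats::rgeom(n, prob = 1 - q)
  pmin(pmax(k, 1), max_cycles)
}
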