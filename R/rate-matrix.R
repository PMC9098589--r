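#' State ordering of the 20-compartment system
#'
#' The state vector holds molar amounts (nmol) in a fixed, documented order:
#' DAR0..DAR8 central, DAR0..DAR8 peripheral, then the DM4 and MeDM4 pools.
#' DAR0 is the naked antibody.
#'
#' @return Character vector of the 20 state names.
#' @export
state_names <- function() {
  c(paste0("DAR", 0:8, "_c"), paste0("DAR", 0:8, "_p"), "DM4", "MeDM4")
}

#' Build the first-order rate matrix of the DAR cascade system
#'
#' Returns the 20 x 20 matrix `A` (units /day) such that between dose events
#' the molar amounts obey `dx/dt = A x`. Each antibody species DARi has
#' two-compartment disposition with shared `V_c`, `V_p`, `Q`; conjugated
#' species (DARi, i >= 1) are eliminated proteolytically at `CL_ADC / V_c`
#' and converted irreversibly to DARi-1 at `kdec_i` in the central
#' compartment, each conversion releasing one DM4 molar equivalent into the
#' DM4 pool; the naked antibody (DAR0) is cleared at `CL_NAB / V_c`. DM4 is
#' eliminated at `CL_DM4 / V_DM4`, a fraction `FR_MeDM4` of that elimination
#' forming MeDM4, itself eliminated at `CL_MeDM4 / V_MeDM4`.
#'
#' @param params an [adc_params()] object.
#' @return A 20 x 20 numeric matrix with `dimnames` from [state_names()].
#' @examples
#' A <- build_rate_matrix(adc_params())
#' A["DM4", "DAR1_c"]  # kdec1
#' @export
build_rate_matrix <- function(params) {
  stopifnot(inherits(params, "adc_params"))
  nm <- state_names()
  A <- matrix(0, 20, 20, dimnames = list(nm, nm))
  kc <- params$q / params$v_c   # central -> peripheral rate
  kp <- params$q / params$v_p   # peripheral -> central rate

  for (i in 0:8) {
    ci <- i + 1L        # central index of DARi
    pi <- i + 10L       # peripheral index of DARi
    cl <- if (i == 0) params$cl_nab else params$cl_adc
    kdec_i <- if (i == 0) 0 else params$kdec[[i]]
    A[ci, ci] <- -(cl / params$v_c + kc + kdec_i)
    A[ci, pi] <- kp
    A[pi, ci] <- kc
    A[pi, pi] <- -kp
    if (i <= 7) A[ci, ci + 1L] <- A[ci, ci + 1L] + params$kdec[[i + 1L]]
    if (i >= 1) A[20 - 1L, ci] <- kdec_i   # DM4 row
  }
  A["DM4", "DM4"] <- -params$cl_dm4 / params$v_dm4
  A["MeDM4", "DM4"] <- params$fr_medm4 * params$cl_dm4 / params$v_dm4
  A["MeDM4", "MeDM4"] <- -params$cl_medm4 / params$v_medm4
  A
}

#' Split an administered dose over the DAR species
#'
#' The administered solution is a mixture of DAR0..DAR8 moieties; the dose is
#' fractioned over the nine central compartments according to the
#' administered dose fractions and delivered as a zero-order infusion.
#'
#' @param params an [adc_params()] object.
#' @param dose_nmol administered molar amount (nmol).
#' @param infusion_duration_h infusion duration in hours.
#' @return A tibble with one row per species: `species`, `fraction`,
#'   `amount_nmol`, and `rate_nmol_day` (the zero-order input rate during
#'   the infusion window).
#' @examples
#' dose_split(adc_params(), 1000, 1)
#' @export
dose_split <- function(params, dose_nmol, infusion_duration_h = 1) {
  stopifnot(inherits(params, "adc_params"))
  if (!is.finite(dose_nmol) || dose_nmol < 0) {
    stop("dose_nmol must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(infusion_duration_h) || infusion_duration_h <= 0) {
    stop("infusion_duration_h must be positive", call. = FALSE)
  }
  if (abs(sum(params$f) - 1) > 1e-9) {
    stop("dose fractions do not sum to 1", call. = FALSE)
  }
  dur_day <- infusion_duration_h / 24
  tibble::tibble(
    species = names(params$f),
    fraction = unname(params$f),
    amount_nmol = unname(params$f) * dose_nmol,
    rate_nmol_day = unname(params$f) * dose_nmol / dur_day
  )
}

#' Per-DAR clearance decomposition
#'
#' For each conjugated species, total ("global") clearance is the sum of the
#' shared proteolytic clearance `CL_ADC` and the deconjugation clearance
#' `kdec_i * V_c`. DAR6, DAR7 and DAR8 share one row because their
#' deconjugation rates are tied.
#'
#' @param params an [adc_params()] object.
#' @return A tibble with columns `dar`, `proteolytic_cl`, `deconjugation_cl`
#'   and `global_cl` (L/day), ordered DAR>=6 down to DAR1.
#' @examples
#' clearance_table(adc_params())
#' @export
clearance_table <- function(params) {
  stopifnot(inherits(params, "adc_params"))
  idx <- 6:1
  tibble::tibble(
    dar = c("DAR>=6", paste0("DAR", 5:1)),
    proteolytic_cl = params$cl_adc,
    deconjugation_cl = unname(params$kdec[idx]) * params$v_c,
    global_cl = params$cl_adc + unname(params$kdec[idx]) * params$v_c
  )
}
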