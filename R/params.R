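#' Structural (fixed-effect) parameters of the DAR-resolved ADC model
#'
#' Constructs the typical-value parameter set of the semi-mechanistic model:
#' nine administered dose fractions (naked antibody DAR0 plus DAR1--DAR8),
#' shared two-compartment disposition of all antibody species, an irreversible
#' first-order central deconjugation cascade, and sequential one-compartment
#' kinetics for the released payload DM4 and its metabolite MeDM4.
#'
#' Defaults are the published population estimates for a DM4
#' antibody-drug conjugate (SPDB linker, average administered DAR 3.8).
#' The deconjugation rates for DAR7 and DAR8 are structurally tied to
#' `kdec6`: those species circulate at trace levels and their conversion
#' rates are not separately identifiable.
#'
#' Dose fractions may be supplied on any scale; they are renormalized to sum
#' exactly to one (the printed estimates sum to 99.8% because of rounding).
#'
#' @param f_nab,f_dar1,f_dar2,f_dar3,f_dar4,f_dar5,f_dar6,f_dar7,f_dar8
#'   administered dose fractions (dimensionless, renormalized to sum to 1).
#' @param cl_adc proteolytic clearance shared by all conjugated species (L/day).
#' @param v_c,v_p central and peripheral volumes (L), shared by all antibody
#'   species including the naked antibody.
#' @param q intercompartmental clearance (L/day).
#' @param kdec1,kdec2,kdec3,kdec4,kdec5,kdec6 first-order deconjugation rate
#'   constants (/day) for DARn -> DARn-1 conversion in the central
#'   compartment; `kdec7` and `kdec8` are always equal to `kdec6`.
#' @param cl_nab naked-antibody clearance (L/day).
#' @param cl_dm4,cl_medm4 apparent clearances of DM4 and MeDM4 (L/day).
#' @param fr_medm4 fraction of DM4 elimination forming MeDM4 (dimensionless).
#' @param v_dm4,v_medm4 reference distribution volumes of DM4 and MeDM4,
#'   fixed to 1 L (formation-limited kinetics make them non-identifiable).
#'
#' @return An object of class `adc_params`: a named list with elements
#'   `f` (length-9 named fraction vector DAR0..DAR8), `kdec` (length-8,
#'   entries 7 and 8 aliased to 6), the clearances and volumes, and the
#'   molecular-weight table used for unit conversion.
#' @examples
#' p <- adc_params()
#' sum(p$f)            # exactly 1
#' clearance_table(p)
#' @export
adc_params <- function(f_nab = 0.071,
                       f_dar1 = 0.085, f_dar2 = 0.175, f_dar3 = 0.218,
                       f_dar4 = 0.199, f_dar5 = 0.142, f_dar6 = 0.071,
                       f_dar7 = 0.028, f_dar8 = 0.009,
                       cl_adc = 0.392, v_c = 3.37, q = 0.543, v_p = 2.54,
                       kdec1 = 0.0565, kdec2 = 0.181, kdec3 = 0.340,
                       kdec4 = 0.525, kdec5 = 0.751, kdec6 = 0.938,
                       cl_nab = 0.408, cl_dm4 = 240, cl_medm4 = 0.256,
                       fr_medm4 = 0.0107, v_dm4 = 1, v_medm4 = 1) {
  f <- c(f_nab, f_dar1, f_dar2, f_dar3, f_dar4, f_dar5, f_dar6, f_dar7, f_dar8)
  names(f) <- paste0("DAR", 0:8)
  if (any(!is.finite(f)) || any(f < 0)) {
    stop("dose fractions must be finite and non-negative", call. = FALSE)
  }
  if (sum(f) <= 0) stop("dose fractions must not all be zero", call. = FALSE)
  f <- f / sum(f)

  kdec <- c(kdec1, kdec2, kdec3, kdec4, kdec5, kdec6, kdec6, kdec6)
  names(kdec) <- paste0("kdec", 1:8)

  pos <- c(cl_adc = cl_adc, v_c = v_c, q = q, v_p = v_p,
           cl_nab = cl_nab, cl_dm4 = cl_dm4, cl_medm4 = cl_medm4,
           v_dm4 = v_dm4, v_medm4 = v_medm4)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    bad <- names(pos)[!is.finite(pos) | pos <= 0]
    stop("parameters must be finite and positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(kdec)) || any(kdec < 0)) {
    stop("deconjugation rates must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(fr_medm4) || fr_medm4 < 0 || fr_medm4 > 1) {
    stop("fr_medm4 must lie in [0, 1]", call. = FALSE)
  }

  structure(
    list(f = f, cl_adc = cl_adc, v_c = v_c, q = q, v_p = v_p, kdec = kdec,
         cl_nab = cl_nab, cl_dm4 = cl_dm4, cl_medm4 = cl_medm4,
         fr_medm4 = fr_medm4, v_dm4 = v_dm4, v_medm4 = v_medm4,
         mw = c(ADC = 150000, NAB = 144522, DM4 = 780, MeDM4 = 794)),
    class = "adc_params"
  )
}

#' @export
print.adc_params <- function(x, ...) {
  cat("<adc_params> DAR-resolved ADC population PK fixed effects\n")
  cat("  dose fractions (%): ",
      paste0(names(x$f), "=", formatC(100 * x$f, format = "fg", digits = 3),
             collapse = " "), "\n")
  cat(sprintf("  CL_ADC %.3g  CL_NAB %.3g  V_c %.3g  V_p %.3g  Q %.3g (L, L/day)\n",
              x$cl_adc, x$cl_nab, x$v_c, x$v_p, x$q))
  cat("  kdec (/day): ", paste(signif(x$kdec[1:6], 3), collapse = " "),
      " (kdec7 = kdec8 = kdec6)\n")
  cat(sprintf("  CL_DM4 %.3g  CL_MeDM4 %.3g  FR_MeDM4 %.3g\n",
              x$cl_dm4, x$cl_medm4, x$fr_medm4))
  invisible(x)
}

#' Update a parameter set
#'
#' Returns a copy of `params` with the named scalar parameters replaced.
#' Fraction updates go through the same renormalization as [adc_params()].
#'
#' @param params an [adc_params()] object.
#' @param ... named replacements, e.g. `cl_adc = 0.5`.
#' @return An `adc_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "adc_params"))
  repl <- list(...)
  args <- list(
    f_nab = params$f[["DAR0"]],
    cl_adc = params$cl_adc, v_c = params$v_c, q = params$q, v_p = params$v_p,
    cl_nab = params$cl_nab, cl_dm4 = params$cl_dm4,
    cl_medm4 = params$cl_medm4, fr_medm4 = params$fr_medm4,
    v_dm4 = params$v_dm4, v_medm4 = params$v_medm4
  )
  for (i in 1:8) args[[paste0("f_dar", i)]] <- params$f[[paste0("DAR", i)]]
  for (i in 1:6) args[[paste0("kdec", i)]] <- params$kdec[[paste0("kdec", i)]]
  unknown <- setdiff(names(repl), names(args))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  args[names(repl)] <- repl
  do.call(adc_params, args)
}

#' Inter-individual variability specification
#'
#' Standard deviations (`omega`) of the log-normal random effects
#' `P_i = P_tv * exp(eta)`, one per structural parameter, plus the dose-fraction
#' variability. All eight deconjugation rates share a single random effect
#' (one `eta_kdec` multiplies `kdec1..kdec8`), reflecting that separate
#' variabilities were not supported by the data. Dose-fraction variability
#' perturbs the DAR0..DAR7 fractions log-normally; the DAR8 fraction is
#' back-calculated as one minus the rest so that every sampled fraction
#' vector still sums to one.
#'
#' Defaults are the published estimates; fraction CVs are the batch
#' coefficients of variation of the administered drug product.
#'
#' @param cl_adc,v_c,q,v_p,kdec,cl_nab,cl_dm4,cl_medm4,fr_medm4 omega values
#'   (standard deviation of the log random effect) for each parameter;
#'   `kdec` is the single shared deconjugation omega.
#' @param f named vector of fraction variabilities (log-sd scale) for
#'   DAR0..DAR7; DAR8 absorbs the closure and has no own variability.
#' @return An object of class `adc_iiv`.
#' @examples
#' iiv <- adc_iiv()
#' iiv$omega[["cl_adc"]]
#' @export
adc_iiv <- function(cl_adc = 0.469, v_c = 0.245, q = 0.529, v_p = 0.605,
                    kdec = 0.202, cl_nab = 0.345, cl_dm4 = 0.365,
                    cl_medm4 = 0.654, fr_medm4 = 0.723,
                    f = c(DAR0 = 0.418, DAR1 = 0.091, DAR2 = 0.091,
                          DAR3 = 0.066, DAR4 = 0.059, DAR5 = 0.102,
                          DAR6 = 0.132, DAR7 = 0.272)) {
  omega <- c(cl_adc = cl_adc, v_c = v_c, q = q, v_p = v_p, kdec = kdec,
             cl_nab = cl_nab, cl_dm4 = cl_dm4, cl_medm4 = cl_medm4,
             fr_medm4 = fr_medm4)
  if (any(!is.finite(omega)) || any(omega < 0)) {
    stop("omega values must be finite and >= 0", call. = FALSE)
  }
  f <- f[paste0("DAR", 0:7)]
  if (anyNA(f) || any(f < 0)) {
    stop("fraction variabilities must be named DAR0..DAR7 and >= 0", call. = FALSE)
  }
  structure(list(omega = omega, f = f), class = "adc_iiv")
}

#' Residual-error specification
#'
#' Entity-specific residual models `Obs = f + (a + b * f) * sigma` with
#' `sigma ~ N(0, 1)`: combined error for the conjugated-antibody (ADC)
#' concentration, proportional error for DM4, MeDM4 and the naked antibody,
#' and additive error for the average DAR and the individual DAR relative
#' proportions (percent scale).
#'
#' Concentration errors act on the assay scale (ADC and NAB in ug/mL,
#' DM4 and MeDM4 in ng/mL); DAR errors act on the natural scale of the
#' derived quantity.
#'
#' @param a_adc additive ADC term (ug/mL).
#' @param b_adc,b_dm4,b_medm4,b_nab proportional terms (dimensionless).
#' @param a_dar_average additive error on the average DAR.
#' @param a_prop named additive errors (percent) for the NAB and DAR1..DAR7
#'   relative-proportion streams.
#' @return An object of class `adc_residual`.
#' @export
adc_residual <- function(a_adc = 1.03, b_adc = 0.089, b_dm4 = 0.335,
                         b_medm4 = 0.500, b_nab = 0.260,
                         a_dar_average = 0.219,
                         a_prop = c(NAB = 9.93, DAR1 = 4.58, DAR2 = 3.48,
                                    DAR3 = 3.26, DAR4 = 2.53, DAR5 = 1.47,
                                    DAR6 = 0.798, DAR7 = 0.517)) {
  vals <- c(a_adc = a_adc, b_adc = b_adc, b_dm4 = b_dm4, b_medm4 = b_medm4,
            b_nab = b_nab, a_dar_average = a_dar_average)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("residual error terms must be finite and >= 0", call. = FALSE)
  }
  a_prop <- a_prop[c("NAB", paste0("DAR", 1:7))]
  if (anyNA(a_prop) || any(a_prop < 0)) {
    stop("a_prop must be named NAB, DAR1..DAR7 and >= 0", call. = FALSE)
  }
  structure(list(a_adc = a_adc, b_adc = b_adc, b_dm4 = b_dm4,
                 b_medm4 = b_medm4, b_nab = b_nab,
                 a_dar_average = a_dar_average, a_prop = a_prop),
            class = "adc_residual")
}

#' Lower-limit-of-quantification rules
#'
#' Assay censoring limits: 0.500 ug/mL for the conjugated antibody,
#' 0.2 ng/mL for DM4 and MeDM4, and a concentration-dependent limit for the
#' naked antibody. The NAB assay requires sample dilution until the
#' co-measured ADC concentration falls below `nab_dilution_threshold`
#' (15 ug/mL); each dilution step inflates the base 1 ug/mL limit, so the
#' effective NAB LLOQ ranges from 1 to `nab_lloq_max` (9.60) ug/mL.
#'
#' @param adc ADC LLOQ (ug/mL).
#' @param dm4,medm4 payload LLOQs (ng/mL).
#' @param nab_base base NAB LLOQ (ug/mL) at dilution factor 1.
#' @param nab_dilution_threshold ADC concentration (ug/mL) above which the
#'   sample must be diluted.
#' @param nab_lloq_max cap on the inflated NAB LLOQ (ug/mL).
#' @return An object of class `adc_lloq`.
#' @export
adc_lloq <- function(adc = 0.500, dm4 = 0.2, medm4 = 0.2,
                     nab_base = 1, nab_dilution_threshold = 15,
                     nab_lloq_max = 9.60) {
  vals <- c(adc, dm4, medm4, nab_base, nab_dilution_threshold, nab_lloq_max)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("LLOQ rule values must be finite and positive", call. = FALSE)
  }
  structure(list(adc = adc, dm4 = dm4, medm4 = medm4, nab_base = nab_base,
                 nab_dilution_threshold = nab_dilution_threshold,
                 nab_lloq_max = nab_lloq_max),
            class = "adc_lloq")
}

#' Bundle fixed effects, variability, residual error and censoring rules
#'
#' A convenience container passed to the trial generator, the estimation
#' routines and the diagnostics.
#'
#' @param params an [adc_params()] object.
#' @param iiv an [adc_iiv()] object.
#' @param residual an [adc_residual()] object.
#' @param lloq an [adc_lloq()] object.
#' @return An object of class `adc_model`.
#' @examples
#' m <- adc_model()
#' m$params$cl_adc
#' @export
adc_model <- function(params = adc_params(), iiv = adc_iiv(),
                      residual = adc_residual(), lloq = adc_lloq()) {
  stopifnot(inherits(params, "adc_params"), inherits(iiv, "adc_iiv"),
            inherits(residual, "adc_residual"), inherits(lloq, "adc_lloq"))
  structure(list(params = params, iiv = iiv, residual = residual, lloq = lloq),
            class = "adc_model")
}

#' @export
print.adc_model <- function(x, ...) {
  cat("<adc_model> fixed effects + IIV + residual error + LLOQ rules\n")
  print(x$params)
  invisible(x)
}
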