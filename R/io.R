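#' Write an observation table as a NONMEM-like CSV
#'
#' Layout: one row per dose event (`EVID=1`, `AMT` in nmol, `RATE` in
#' nmol/day) or observation (`EVID=0`, `DV` on the assay scale), with
#' string entity codes (numeric aliases in [entity_codes()]), BLQ flags
#' carrying their LLOQ, and times in days.
#'
#' @param data an `adc_trial` or its observation tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  obs <- if (inherits(data, "adc_trial")) data$observations else
    tibble::as_tibble(data)
  out <- tibble::tibble(
    ID = obs$id, COHORT = obs$cohort, TIME = obs$time, EVID = obs$evid,
    AMT = obs$amt, RATE = obs$rate, MDV = obs$mdv, ENTITY = obs$entity,
    DV = obs$dv, BLQ = as.integer(obs$blq), LLOQ = obs$lloq,
    UNITS = obs$units, BSA = obs$bsa
  )
  readr::write_csv(out, path, na = ".")
  invisible(path)
}

#' Read a NONMEM-like observation CSV
#'
#' Validates the dialect written by [write_dataset()]: required columns,
#' known entity codes, `AMT > 0` with `MDV = 1` on dose rows, and an LLOQ
#' on every BLQ row. Malformed rows are reported with their line numbers.
#'
#' @param path CSV path.
#' @return The observation tibble (columns `id`, `cohort`, `time`, `evid`,
#'   `amt`, `rate`, `mdv`, `entity`, `dv`, `blq`, `lloq`, `units`, `bsa`).
#' @export
read_dataset <- function(path) {
  raw <- readr::read_csv(path, na = ".", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("ID", "TIME", "EVID", "AMT", "RATE", "MDV", "ENTITY", "DV",
            "BLQ", "LLOQ")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  codes <- c(entity_codes()$entity, "DOSE")
  bad <- which(!raw$ENTITY %in% codes)
  if (length(bad)) {
    stop("invalid entity code(s) on data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  dose <- raw$EVID == 1
  bad <- which(dose & (is.na(raw$AMT) | raw$AMT <= 0 | raw$MDV != 1))
  if (length(bad)) {
    stop("dose rows must have AMT > 0 and MDV = 1; offending row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!dose & raw$BLQ == 1 & is.na(raw$LLOQ))
  if (length(bad)) {
    stop("BLQ rows must carry their LLOQ; offending row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    id = raw$ID,
    cohort = if ("COHORT" %in% names(raw)) raw$COHORT else NA_character_,
    time = raw$TIME, evid = as.integer(raw$EVID), amt = raw$AMT,
    rate = raw$RATE, mdv = as.integer(raw$MDV), entity = raw$ENTITY,
    dv = raw$DV, blq = raw$BLQ == 1, lloq = raw$LLOQ,
    units = if ("UNITS" %in% names(raw)) raw$UNITS else NA_character_,
    bsa = if ("BSA" %in% names(raw)) raw$BSA else 1.8
  )
  message(sprintf("read %d rows: %d dose events, %d observations (%d BLQ)",
                  nrow(out), sum(out$evid == 1), sum(out$evid == 0),
                  sum(out$blq)))
  out
}

#' Read a structured model/trial configuration
#'
#' YAML file with sections `fixed_effects`, `iiv`, `residual_error`,
#' `lloq`, `regimen` and `design` (each optional except `fixed_effects`;
#' unknown sections or keys are rejected). The shipped default
#' (`system.file("extdata", "default_config.yaml", package = "darpk")`)
#' encodes the published estimates.
#'
#' @param path YAML path.
#' @return A list with `model` ([adc_model()]), `regimen`
#'   ([adc_regimen()] or NULL) and `design` ([trial_design()]).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("fixed_effects", "iiv", "residual_error", "lloq", "regimen",
             "design")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) {
      stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(cfg$fixed_effects)) stop("config lacks fixed_effects", call. = FALSE)
  check_keys(cfg$fixed_effects, names(formals(adc_params)), "fixed_effects")
  params <- do.call(adc_params, cfg$fixed_effects)

  iiv <- adc_iiv()
  if (!is.null(cfg$iiv)) {
    check_keys(cfg$iiv, names(formals(adc_iiv)), "iiv")
    if (!is.null(cfg$iiv$f)) cfg$iiv$f <- unlist(cfg$iiv$f)
    iiv <- do.call(adc_iiv, cfg$iiv)
  }
  res <- adc_residual()
  if (!is.null(cfg$residual_error)) {
    check_keys(cfg$residual_error, names(formals(adc_residual)), "residual_error")
    if (!is.null(cfg$residual_error$a_prop)) {
      cfg$residual_error$a_prop <- unlist(cfg$residual_error$a_prop)
    }
    res <- do.call(adc_residual, cfg$residual_error)
  }
  lloq <- adc_lloq()
  if (!is.null(cfg$lloq)) {
    check_keys(cfg$lloq, names(formals(adc_lloq)), "lloq")
    lloq <- do.call(adc_lloq, cfg$lloq)
  }
  regimen <- NULL
  if (!is.null(cfg$regimen)) {
    check_keys(cfg$regimen, names(formals(adc_regimen)), "regimen")
    if (is.null(cfg$regimen$bsa)) {
      message("regimen bsa not given; using default 1.8 m^2")
    }
    regimen <- do.call(adc_regimen, cfg$regimen)
  }
  design <- trial_design()
  if (!is.null(cfg$design)) {
    check_keys(cfg$design,
               setdiff(names(formals(trial_design)), "cohorts"), "design")
    cfg$design$bsa_range <- if (is.null(cfg$design$bsa_range)) c(1.2, 2.4)
      else unlist(cfg$design$bsa_range)
    design <- do.call(trial_design, cfg$design)
  }
  list(model = adc_model(params, iiv, res, lloq), regimen = regimen,
       design = design)
}
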