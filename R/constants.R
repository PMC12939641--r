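#' Monitored vital-sign channels
#'
#' Column names of the 1 Hz vitals table: heart rate (beats/min), systolic /
#' mean / diastolic arterial pressure (mmHg), respiratory rate (breaths/min),
#' arterial saturation (%), central venous pressure (mmHg), cerebral and renal
#' near-infrared spectroscopy (%).
#'
#' @return Character vector of signal column names.
#' @export
vital_signals <- function() {
  c("hr", "sbp", "map", "dbp", "rr", "sao2", "cvp", "cnirs", "rnirs")
}

#' Vasoactive infusions and their native dose units
#'
#' The eight continuous vasoactive infusions tracked by the pipeline.
#' Epinephrine, norepinephrine, milrinone, nitroprusside, nicardipine and
#' phenylephrine are dosed in mcg/kg/min; calcium chloride in mg/kg/hr;
#' vasopressin in milliunits/kg/min.
#'
#' @return Named character vector: names are drug identifiers, values units.
#' @export
drug_units <- function() {
  c(epinephrine      = "mcg/kg/min",
    norepinephrine   = "mcg/kg/min",
    milrinone        = "mcg/kg/min",
    vasopressin      = "milliunits/kg/min",
    phenylephrine    = "mcg/kg/min",
    calcium_chloride = "mg/kg/hr",
    nitroprusside    = "mcg/kg/min",
    nicardipine      = "mcg/kg/min")
}

#' @rdname drug_units
#' @export
drug_names <- function() names(drug_units())

#' Derived hemodynamic outcomes
#'
#' The six derived outcomes modelled per patient-time point: mean circulatory
#' filling pressure (mmHg), venous resistance (mmHg per L/min), indexed
#' systemic vascular resistance (dyn s cm-5 m2), cardiac index (L/min/m2),
#' and cerebral / renal oxygen extraction (fraction).
#'
#' @return Character vector of outcome column names.
#' @export
outcome_names <- function() {
  c("mcfp", "rv", "svri", "ci", "coer", "roer")
}

#' Model feature set
#'
#' Predictors used by every outcome model: relative time, encoded patient
#' identifier, age, weight, and the eight vasoactive infusion doses.
#'
#' @return Character vector of feature column names.
#' @export
feature_names <- function() {
  c("time_s", "patient_id", "age_years", "weight_kg", drug_names())
}

# analysis window: first 48 postoperative hours, half-open [0, 172800)
WINDOW_S <- 172800L

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(field, "must be a single finite number")
  if (strict_lower && x <= lower)
    stop_config(field, sprintf("must be > %g", lower))
  if (!strict_lower && x < lower)
    stop_config(field, sprintf("must be >= %g", lower))
  if (x > upper) stop_config(field, sprintf("must be <= %g", upper))
  invisible(x)
}
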