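#' Default drug effect specification
#'
#' Signed asymptotic effects (signal units at full receptor saturation) of
#' each vasoactive infusion on each raw monitored signal, together with the
#' half-saturation dose `k_half` of the monotone saturating dose transform
#' `sat(d) = d / (d + k_half)`. Effects are instantaneous functions of the
#' current dose (no pharmacokinetics).
#'
#' The matrix encodes the qualitative pharmacology of a post-transplant
#' cohort: epinephrine, norepinephrine and vasopressin venoconstrict (CVP and
#' MCFP rise); milrinone and nitroprusside venodilate and arteriodilate;
#' nicardipine is arterial-selective; calcium chloride mainly augments
#' regional oxygen delivery; phenylephrine carries an all-zero dose column by
#' default and hence no effect. The derived-outcome sign matrix these
#' defaults encode is exported as [reference_directions()].
#'
#' @param dose_ranges named list of `c(min, max)` dose ranges per drug, used
#'   to place `k_half` at the mid-range dose
#' @return List with `deltas` (drug x signal matrix) and `k_half` (named
#'   vector, native dose units).
#' @export
default_effect_spec <- function(dose_ranges = default_dose_schedule()$ranges) {
  sigs <- vital_signals()
  drugs <- drug_names()
  m <- matrix(0, nrow = length(drugs), ncol = length(sigs),
              dimnames = list(drugs, sigs))
  set_fx <- function(drug, hr = 0, map = 0, cvp = 0, cnirs = 0, rnirs = 0) {
    m[drug, c("hr", "sbp", "map", "dbp", "cvp", "cnirs", "rnirs")] <<-
      c(hr, 1.4 * map, map, 0.7 * map, cvp, cnirs, rnirs)
  }
  set_fx("epinephrine",      hr = 20, map = 12,  cvp = 2.5,  cnirs = 3,    rnirs = 1)
  set_fx("norepinephrine",   hr = 5,  map = 12,  cvp = 3,    cnirs = -2,   rnirs = -2)
  set_fx("milrinone",        hr = 5,  map = -6,  cvp = -2,   cnirs = 4,    rnirs = 4)
  set_fx("vasopressin",      hr = -5, map = 10,  cvp = 2.5,  cnirs = -2,   rnirs = -2)
  set_fx("calcium_chloride",                     cnirs = 2,  rnirs = 3.5)
  set_fx("nitroprusside",    hr = 8,  map = -10, cvp = -2.5, cnirs = 3,    rnirs = 3)
  set_fx("nicardipine",      hr = 8,  map = -12,             cnirs = 2.5,  rnirs = 2)
  k <- vapply(drugs, function(d) max(dose_ranges[[d]]) / 2, numeric(1))
  list(deltas = m, k_half = k)
}

#' Default slow postoperative time trends (signal units per hour)
#'
#' Encodes gradual recovery over the first 48 h: heart rate drifts down,
#' arterial pressure drifts up, CVP falls slowly, and NIRS channels rise as
#' oxygen delivery improves.
#'
#' @return Named numeric vector over [vital_signals()].
#' @export
default_time_trend <- function() {
  c(hr = -0.3, sbp = 0.07, map = 0.05, dbp = 0.03, rr = 0, sao2 = 0,
    cvp = -0.05, cnirs = 0.1, rnirs = 0.1)
}

#' Default AR(1) noise configuration
#'
#' Per-signal first-order autoregressive noise: `e_t = phi * e_(t-1) + z_t`,
#' `z_t ~ N(0, sd^2)`. `phi` is defined per sample step; the stationary
#' standard deviation is `sd / sqrt(1 - phi^2)`.
#'
#' @return List with named vectors `phi` and `sd` over [vital_signals()].
#' @export
default_noise <- function() {
  sigs <- vital_signals()
  phi <- stats::setNames(rep(0.9, length(sigs)), sigs)
  sd <- c(hr = 1.5, sbp = 2, map = 1.5, dbp = 1.5, rr = 1, sao2 = 0.4,
          cvp = 0.6, cnirs = 1, rnirs = 1)
  list(phi = phi, sd = sd[sigs])
}

#' Default infusion dose schedule configuration
#'
#' Piecewise-constant schedules with a Poisson number of dose changes per
#' 48 h window; each segment is zero with probability `p_zero`, otherwise
#' uniform over the drug's clinical dose range (native units; see
#' [drug_units()]). Phenylephrine defaults to a degenerate `[0, 0]` range,
#' i.e. a structurally present but never-dosed column.
#'
#' @return List: `mean_changes`, `p_zero`, `ranges` (named list per drug).
#' @export
default_dose_schedule <- function() {
  list(
    mean_changes = 6,
    p_zero = 0.3,
    ranges = list(
      epinephrine      = c(0, 0.1),
      norepinephrine   = c(0, 0.1),
      milrinone        = c(0, 1),
      vasopressin      = c(0, 1.2),
      phenylephrine    = c(0, 0),
      calcium_chloride = c(0, 20),
      nitroprusside    = c(0, 3),
      nicardipine      = c(0, 3)
    )
  )
}

#' Default physiologic clip bounds per signal
#'
#' @return Named list of `c(lower, upper)` per signal.
#' @export
default_clip_bounds <- function() {
  list(hr = c(40, 220), sbp = c(30, 180), map = c(25, 130), dbp = c(15, 110),
       rr = c(5, 80), sao2 = c(50, 100), cvp = c(0, 30),
       cnirs = c(15, 95), rnirs = c(15, 95))
}

#' Synthetic cohort configuration
#'
#' Bundles and validates everything the generator needs. Defaults emulate the
#' study conditions: 1 Hz sampling over the first 48 postoperative hours,
#' eight vasoactive infusions with monotone saturating effects, slow
#' postoperative trends, AR(1) noise and MCAR missingness.
#'
#' @param n_patients number of patients (>= 1)
#' @param duration_s record length in seconds (default 172800 = 48 h); must
#'   be a positive multiple of `sample_interval_s`
#' @param sample_interval_s sampling interval in seconds (default 1)
#' @param drugs character vector of drug names (must be a subset of
#'   [drug_names()])
#' @param effect_spec see [default_effect_spec()]
#' @param time_trend see [default_time_trend()]
#' @param noise see [default_noise()]; all AR coefficients must lie in `[0, 1)`
#' @param missing_rate MCAR cell-missingness fraction in `[0, 1)`
#' @param dose_schedule see [default_dose_schedule()]
#' @param clip_bounds see [default_clip_bounds()]
#' @param seed master seed; one RNG stream per patient is derived from it by
#'   a fixed offset, so patient k is reproducible independently of cohort size
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_patients,
                         duration_s = 172800,
                         sample_interval_s = 1,
                         drugs = drug_names(),
                         effect_spec = NULL,
                         time_trend = default_time_trend(),
                         noise = default_noise(),
                         missing_rate = 0.05,
                         dose_schedule = default_dose_schedule(),
                         clip_bounds = default_clip_bounds(),
                         seed = 1L) {
  check_scalar_num(n_patients, "n_patients", lower = 1)
  check_scalar_num(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_scalar_num(sample_interval_s, "sample_interval_s", lower = 0,
                   strict_lower = TRUE)
  if (abs(duration_s / sample_interval_s -
          round(duration_s / sample_interval_s)) > 1e-9)
    stop_config("duration_s", "must be a multiple of sample_interval_s")
  unknown <- setdiff(drugs, drug_names())
  if (length(unknown))
    stop_config("drugs", paste0("contains unknown drug(s): ",
                                paste(unknown, collapse = ", "),
                                "; known drugs are: ",
                                paste(drug_names(), collapse = ", ")))
  check_scalar_num(missing_rate, "missing_rate", lower = 0)
  if (missing_rate >= 1) stop_config("missing_rate", "must be < 1")
  if (any(noise$phi < 0 | noise$phi >= 1))
    stop_config("noise$phi", "AR(1) coefficients must lie in [0, 1)")
  if (any(noise$sd < 0)) stop_config("noise$sd", "must be non-negative")
  for (d in drugs) {
    r <- dose_schedule$ranges[[d]]
    if (is.null(r) || length(r) != 2L || any(r < 0) || r[2] < r[1])
      stop_config(paste0("dose_schedule$ranges$", d),
                  "must be a non-negative c(min, max) range")
  }
  if (dose_schedule$mean_changes < 0)
    stop_config("dose_schedule$mean_changes", "must be non-negative")
  if (is.null(effect_spec))
    effect_spec <- default_effect_spec(dose_schedule$ranges)
  check_scalar_num(seed, "seed")
  structure(list(
    n_patients = as.integer(n_patients), duration_s = duration_s,
    sample_interval_s = sample_interval_s, drugs = drugs,
    effect_spec = effect_spec, time_trend = time_trend, noise = noise,
    missing_rate = missing_rate, dose_schedule = dose_schedule,
    clip_bounds = clip_bounds, seed = as.integer(seed)
  ), class = "synth_config")
}

# fixed-offset per-patient seed derived from the master seed
patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * i) %% 2147483587L) + 1L
}

time_grid <- function(config) {
  n <- as.integer(round(config$duration_s / config$sample_interval_s))
  seq(0, by = config$sample_interval_s, length.out = n)
}

# sample one patient profile from age-stratified post-transplant baselines;
# uses the current RNG stream
sample_profile <- function(patient_id) {
  stratum <- sample.int(4L, 1L, prob = c(0.22, 0.24, 0.11, 0.43))
  age <- switch(stratum,
                stats::runif(1, 0.1, 1),
                stats::runif(1, 1, 5),
                stats::runif(1, 6, 10),
                stats::runif(1, 10, 18))
  weight <- if (age < 1) 3.5 + 5.5 * age else 2.3 * age + 8
  weight <- weight * exp(stats::rnorm(1, 0, 0.12))
  height <- if (age < 1) 50 + 26 * age else 80 + 5.8 * age
  height <- height * exp(stats::rnorm(1, 0, 0.04))
  data.frame(
    patient_id = patient_id,
    age_years = age,
    weight_kg = weight,
    height_cm = height,
    bsa_m2 = bsa_mosteller(height, weight),
    single_ventricle = stats::rbinom(1, 1, 0.3),
    critical_illness = 1L,
    hemoglobin_g_dl = stats::runif(1, 10, 15)
  )
}

# age-stratified baseline means for the raw signals; current RNG stream
sample_baseline <- function(age_years) {
  hr0 <- if (age_years < 1) 130 else if (age_years < 6) 110 else
         if (age_years <= 10) 100 else 90
  rr0 <- if (age_years < 1) 35 else if (age_years < 6) 28 else
         if (age_years <= 10) 22 else 16
  map <- stats::runif(1, 55, 75)
  c(hr = hr0 + stats::runif(1, -10, 10),
    sbp = map + stats::runif(1, 15, 30),
    map = map,
    dbp = map - stats::runif(1, 8, 15),
    rr = rr0 + stats::runif(1, -4, 4),
    sao2 = stats::runif(1, 96, 100),
    cvp = stats::runif(1, 6, 12),
    cnirs = stats::runif(1, 60, 80),
    rnirs = stats::runif(1, 55, 80))
}

#' Saturating dose transform
#'
#' `sat(d) = d / (d + k_half)`: monotone non-decreasing, `sat(0) = 0`,
#' asymptote 1. A non-positive `k_half` (degenerate never-dosed drug) maps
#' every dose to 0.
#'
#' @param dose non-negative dose vector
#' @param k_half half-saturation dose (native units)
#' @return Values in `[0, 1)`.
#' @export
saturating_dose <- function(dose, k_half) {
  if (k_half <= 0) return(rep(0, length(dose)))
  dose / (dose + k_half)
}

#' Generate one drug's piecewise-constant dose schedule
#'
#' Draws a Poisson number of change-points (mean scaled to the configured
#' rate per 48 h), uniform change times, and per-segment doses that are zero
#' with probability `p_zero` and otherwise uniform over the drug's range.
#' Uses the current RNG stream; seed before calling for reproducibility.
#'
#' @param drug drug name (must be in `config$drugs`)
#' @param config a [synth_config()]
#' @return Numeric dose vector on the configuration's time grid.
#' @export
generate_dose_schedule <- function(drug, config) {
  if (!drug %in% config$drugs)
    stop("unknown drug '", drug, "'; known drugs: ",
         paste(config$drugs, collapse = ", "), call. = FALSE)
  tg <- time_grid(config)
  sched <- config$dose_schedule
  r <- sched$ranges[[drug]]
  lambda <- sched$mean_changes * config$duration_s / 172800
  n_change <- stats::rpois(1, lambda)
  breaks <- sort(stats::runif(n_change, 0, config$duration_s))
  n_seg <- n_change + 1L
  seg_dose <- ifelse(stats::runif(n_seg) < sched$p_zero, 0,
                     stats::runif(n_seg, r[1], r[2]))
  seg_idx <- findInterval(tg, breaks) + 1L
  seg_dose[seg_idx]
}

#' Apply the dose-effect model to baseline signals
#'
#' The expected value of each signal at time t is
#' `baseline + trend * t_hours + sum over drugs of delta * sat(dose_t)`,
#' where `sat` is the monotone saturating transform with `sat(0) = 0`.
#' AR(1) noise (initialised at its stationary distribution) is added around
#' that mean and the result clipped to physiologic bounds. Uses the current
#' RNG stream.
#'
#' @param baseline named numeric vector of per-patient baseline signal values
#' @param doses dose frame (`time_s` plus one column per drug) on the target
#'   time grid
#' @param effect_spec list with `deltas` matrix and `k_half` vector, as from
#'   [default_effect_spec()]
#' @param time_trend named vector, signal units per hour
#' @param noise list with named `phi` and `sd` vectors
#' @param clip_bounds named list of `c(lower, upper)` per signal
#' @return Vitals data frame: `time_s` plus [vital_signals()].
#' @export
apply_effect_model <- function(baseline, doses, effect_spec,
                               time_trend = default_time_trend(),
                               noise = default_noise(),
                               clip_bounds = default_clip_bounds()) {
  sigs <- vital_signals()
  if (!all(sigs %in% names(baseline)))
    stop("baseline must name every signal in vital_signals()", call. = FALSE)
  tg <- doses$time_s
  if (is.null(tg) || is.unsorted(tg, strictly = TRUE))
    stop("doses must carry a strictly increasing time_s column",
         call. = FALSE)
  n <- length(tg)
  drugs_here <- intersect(rownames(effect_spec$deltas), names(doses))
  # precompute per-drug saturation once; columns indexed by drug name
  sat <- matrix(0, nrow = n, ncol = length(drugs_here),
                dimnames = list(NULL, drugs_here))
  for (d in drugs_here)
    sat[, d] <- saturating_dose(doses[[d]], effect_spec$k_half[[d]])
  out <- data.frame(time_s = tg)
  t_h <- tg / 3600
  for (s in sigs) {
    mu <- baseline[[s]] + (time_trend[[s]] %||% 0) * t_h
    for (d in drugs_here) {
      delta <- effect_spec$deltas[d, s]
      if (delta != 0) mu <- mu + delta * sat[, d]
    }
    sdv <- noise$sd[[s]] %||% 0
    if (sdv > 0) {
      phi <- noise$phi[[s]] %||% 0
      innov <- stats::rnorm(n, 0, sdv)
      e0 <- stats::rnorm(1, 0, sdv / sqrt(1 - phi^2))
      e <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                    init = e0))
      mu <- mu + e
    }
    b <- clip_bounds[[s]]
    if (!is.null(b)) mu <- pmin(pmax(mu, b[1]), b[2])
    out[[s]] <- mu
  }
  out
}

#' Inject MCAR missingness into a vitals frame
#'
#' Each signal cell is set absent independently with probability `rate`;
#' the time column is never touched. Uses the current RNG stream.
#'
#' @param vitals vitals frame
#' @param rate missingness probability in `[0, 1)`
#' @return Vitals frame with `NA` cells.
#' @export
inject_missingness <- function(vitals, rate) {
  check_scalar_num(rate, "missing_rate", lower = 0)
  if (rate >= 1) stop_config("missing_rate", "must be < 1")
  if (rate == 0) return(vitals)
  for (s in intersect(vital_signals(), names(vitals))) {
    hit <- stats::runif(nrow(vitals)) < rate
    vitals[[s]][hit] <- NA_real_
  }
  vitals
}

#' Generate a synthetic post-transplant cohort
#'
#' Produces, for each patient, a profile, a piecewise-constant dose frame for
#' every configured drug, and a vitals frame whose signals respond to dose
#' with the configured monotone saturating effects, drift with the
#' postoperative trend, carry AR(1) noise, and contain MCAR missingness.
#' Each patient uses an RNG stream derived from the master seed by a fixed
#' offset, so outputs are bit-for-bit reproducible and patient k does not
#' change when the cohort grows.
#'
#' @param config a [synth_config()]
#' @return Object of class `synth_cohort`: `profiles` (one row per patient),
#'   `vitals` and `doses` (lists of data frames, one per patient, identical
#'   time grids starting at 0), and the `config` echo.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config"))
    config <- do.call(synth_config, config)
  profiles <- vector("list", config$n_patients)
  vitals <- vector("list", config$n_patients)
  doses <- vector("list", config$n_patients)
  tg <- time_grid(config)
  for (i in seq_len(config$n_patients)) {
    set.seed(patient_seed(config$seed, i))
    prof <- sample_profile(sprintf("P%03d", i))
    base <- sample_baseline(prof$age_years)
    df <- data.frame(time_s = tg)
    for (d in config$drugs) df[[d]] <- generate_dose_schedule(d, config)
    v <- apply_effect_model(base, df, config$effect_spec, config$time_trend,
                            config$noise, config$clip_bounds)
    v <- inject_missingness(v, config$missing_rate)
    profiles[[i]] <- prof
    vitals[[i]] <- v
    doses[[i]] <- df
  }
  profiles <- do.call(rbind, profiles)
  names(vitals) <- profiles$patient_id
  names(doses) <- profiles$patient_id
  structure(list(profiles = profiles, vitals = vitals, doses = doses,
                 config = config),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d patients, %d rows each (%.1f h at %g s intervals)\n",
    nrow(x$profiles), nrow(x$vitals[[1]]),
    x$config$duration_s / 3600, x$config$sample_interval_s))
  invisible(x)
}

#' Derived-outcome direction matrix encoded by the generator defaults
#'
#' The ground-truth sign (+1 increase, -1 decrease, 0 neutral) of each
#' drug's effect on each derived outcome under [default_effect_spec()],
#' obtained by propagating the raw-signal effects through the derivation
#' formulas at a reference patient.
#'
#' The MCFP and venous-resistance columns encode the study's reported
#' direction-of-effect calls. Because venous resistance and SVRi are
#' affinely coupled under the derivation formulas
#' (`Rv = SVRi / (2000 * BSA) + 0.2` when venous return equals cardiac
#' output), not every reported arterial-side call can coexist with the
#' venous-side calls; where they conflict the venous columns take precedence
#' and the remaining columns follow the formula coupling. See the methods
#' vignette.
#'
#' @return Integer matrix, drugs x outcomes, entries in `{-1, 0, 1}`.
#' @export
reference_directions <- function() {
  out <- outcome_names()
  m <- matrix(0L, nrow = length(drug_names()), ncol = length(out),
              dimnames = list(drug_names(), out))
  m["epinephrine", ]      <- c( 1L,  1L,  1L,  1L, -1L, -1L)
  m["norepinephrine", ]   <- c( 1L,  1L,  1L, -1L,  1L,  1L)
  m["milrinone", ]        <- c(-1L, -1L, -1L,  1L, -1L, -1L)
  m["vasopressin", ]      <- c( 1L,  1L,  1L, -1L,  1L,  1L)
  m["phenylephrine", ]    <- c( 0L,  0L,  0L,  0L,  0L,  0L)
  m["calcium_chloride", ] <- c( 0L, -1L, -1L,  1L, -1L, -1L)
  m["nitroprusside", ]    <- c(-1L, -1L, -1L,  1L, -1L, -1L)
  m["nicardipine", ]      <- c(-1L, -1L, -1L,  1L, -1L, -1L)
  m
}
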