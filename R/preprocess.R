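#' Normalize timestamps to seconds relative to admission
#'
#' Shifts raw timestamps so that ICU admission is time 0, keeps whole
#' seconds, and drops records outside the half-open analysis window
#' `[0, window_s)` (default the first 48 postoperative hours).
#'
#' @param raw_timestamps numeric seconds or POSIXct
#' @param admission_timestamp admission time on the same scale
#' @param window_s analysis window length in seconds
#' @return Integer-valued relative seconds, pre-admission and post-window
#'   records removed; warns when nothing is retained.
#' @export
normalize_time <- function(raw_timestamps, admission_timestamp,
                           window_s = WINDOW_S) {
  rel <- as.numeric(raw_timestamps) - as.numeric(admission_timestamp)
  rel <- floor(rel)
  keep <- rel >= 0 & rel < window_s
  out <- rel[keep]
  if (length(out) == 0L)
    warning("no records fall inside [0, ", window_s,
            ") relative to admission", call. = FALSE)
  out
}

#' Collate medication-administration events onto a time grid
#'
#' Builds the piecewise-constant dose frame implied by administration
#' records: the dose at time t is the most recently recorded dose at or
#' before t (last observation carried forward), zero before a drug's first
#' record, and a recorded stop (dose 0) propagates until the next record.
#'
#' @param events data frame with columns `time_s`, `drug`, `dose` and
#'   optionally `unit`; if `unit` is present it is validated against
#'   [drug_units()]
#' @param grid numeric vector of output times (strictly increasing)
#' @param drugs drug columns to emit (default all eight)
#' @return Dose frame: `time_s` plus one column per drug.
#' @export
collate_doses <- function(events, grid, drugs = drug_names()) {
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing", call. = FALSE)
  if (nrow(events) > 0) {
    if (any(!is.finite(events$dose) | events$dose < 0))
      stop("dose events must be finite and non-negative", call. = FALSE)
    unknown <- setdiff(unique(events$drug), drug_names())
    if (length(unknown))
      stop("unknown drug(s) in events: ", paste(unknown, collapse = ", "),
           "; known drugs: ", paste(drug_names(), collapse = ", "),
           call. = FALSE)
    if (!is.null(events$unit)) {
      exp_unit <- drug_units()[events$drug]
      bad <- events$unit != exp_unit
      if (any(bad))
        stop("dose unit mismatch for ",
             paste(unique(events$drug[bad]), collapse = ", "),
             " (expected ", paste(unique(exp_unit[bad]), collapse = ", "),
             ")", call. = FALSE)
    }
    events <- events[order(events$time_s), , drop = FALSE]
  }
  out <- data.frame(time_s = grid)
  for (d in drugs) {
    ev <- events[events$drug == d, , drop = FALSE]
    if (nrow(ev) == 0L) {
      out[[d]] <- rep(0, length(grid))
    } else {
      idx <- findInterval(grid, ev$time_s)   # 0 before first event
      out[[d]] <- c(0, ev$dose)[idx + 1L]
    }
  }
  out
}

#' Impute missing vitals with patient-specific medians
#'
#' Replaces each absent cell of a signal by the median of that patient's
#' observed values of the same signal (even counts: mean of the two central
#' values). The frame must belong to a single patient; no cross-patient
#' pooling occurs. Signals with no observed values at all are left absent
#' and flagged in the `fully_missing` attribute.
#'
#' @param vitals one patient's vitals frame
#' @return Imputed frame with attribute `fully_missing` (character vector of
#'   signals that could not be imputed).
#' @export
impute_patient_median <- function(vitals) {
  fully <- character(0)
  for (s in intersect(vital_signals(), names(vitals))) {
    x <- vitals[[s]]
    nas <- is.na(x)
    if (!any(nas)) next
    if (all(nas)) {
      fully <- c(fully, s)
      next
    }
    x[nas] <- stats::median(x[!nas])
    vitals[[s]] <- x
  }
  attr(vitals, "fully_missing") <- fully
  vitals
}

#' Assemble the model feature table
#'
#' Inner-joins profiles, dose frames and derived outcomes on
#' (patient, time_s) into one modelling table: features `time_s`,
#' `patient_id` (integer-ordinal encoding in profile order), `age_years`,
#' `weight_kg` and the eight drug doses; one target column per derived
#' outcome. Rows whose derived outcomes carry undefined flags (NA) are
#' dropped and counted in the `n_dropped` attribute so that the table holds
#' no absent values. Output is sorted by (patient_id, time_s) and hence
#' deterministic under input row shuffling.
#'
#' @param profiles patient profile table
#' @param doses named list of dose frames (one per patient)
#' @param derived named list of derived frames (one per patient, as from
#'   [derive_all()])
#' @return Feature table data frame with attribute `n_dropped`.
#' @export
build_feature_table <- function(profiles, doses, derived) {
  targets <- outcome_names()
  pieces <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    pid <- profiles$patient_id[i]
    dfd <- doses[[pid]]
    dvd <- derived[[pid]]
    if (is.null(dfd) || is.null(dvd))
      stop("missing dose or derived frame for patient ", pid, call. = FALSE)
    m <- match(dfd$time_s, dvd$time_s)
    if (anyNA(m))
      stop("derived outcomes missing for some (patient, time) rows of ",
           pid, ": frames are misaligned", call. = FALSE)
    piece <- data.frame(
      time_s = dfd$time_s,
      patient_id = i,
      age_years = profiles$age_years[i],
      weight_kg = profiles$weight_kg[i]
    )
    for (d in drug_names()) piece[[d]] <- dfd[[d]] %||% 0
    for (y in targets) piece[[y]] <- dvd[[y]][m]
    pieces[[i]] <- piece
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$patient_id, out$time_s), , drop = FALSE]
  keep <- stats::complete.cases(out[, targets, drop = FALSE])
  n_dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}
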