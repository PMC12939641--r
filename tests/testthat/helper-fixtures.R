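# shared fixtures, built in code

ref_profile <- function(age = 5, weight = 19.5, height = 109, sv = 0, ci = 1,
                        hb = 13) {
  data.frame(patient_id = "ref", age_years = age, weight_kg = weight,
             height_cm = height, bsa_m2 = bsa_mosteller(height, weight),
             single_ventricle = sv, critical_illness = ci,
             hemoglobin_g_dl = hb)
}

ref_baseline <- function() {
  c(hr = 110, sbp = 85, map = 65, dbp = 55, rr = 28, sao2 = 98, cvp = 9,
    cnirs = 70, rnirs = 65)
}

# a small, fast cohort configuration for structural tests
small_config <- function(n_patients = 2, duration_s = 600,
                         sample_interval_s = 1, seed = 7, ...) {
  synth_config(n_patients = n_patients, duration_s = duration_s,
               sample_interval_s = sample_interval_s, seed = seed, ...)
}

# constant-signal vitals frame for formula tests
const_vitals <- function(n = 5, map = 65, cvp = 9, sao2 = 98, cnirs = 70,
                         rnirs = 65) {
  data.frame(time_s = seq_len(n) - 1, hr = 110, sbp = 85, map = map, rr = 28,
             dbp = 55, sao2 = sao2, cvp = cvp, cnirs = cnirs, rnirs = rnirs)
}

# feature-table skeleton with controllable targets, for modeling tests
toy_feature_table <- function(n, seed = 1) {
  set.seed(seed)
  ft <- data.frame(
    time_s = seq_len(n),
    patient_id = sample(1:5, n, replace = TRUE),
    age_years = stats::runif(n, 1, 15),
    weight_kg = stats::runif(n, 8, 60)
  )
  for (d in drug_names()) ft[[d]] <- stats::runif(n, 0, 1)
  ft$phenylephrine <- 0
  ft
}
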