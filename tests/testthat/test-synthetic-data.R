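test_that("cohort generation honours the grid and is seed-deterministic", {
  cfg <- small_config(n_patients = 2, duration_s = 600, seed = 7)
  ch <- generate_cohort(cfg)
  expect_length(ch$vitals, 2)
  for (v in ch$vitals) {
    expect_equal(nrow(v), 600)
    expect_equal(v$time_s, 0:599)
    expect_false(is.unsorted(v$time_s, strictly = TRUE))
  }
  ch2 <- generate_cohort(small_config(n_patients = 2, duration_s = 600,
                                      seed = 7))
  expect_identical(ch, ch2)
  # patient-level reproducibility: patient 1 unchanged when the cohort grows
  ch3 <- generate_cohort(small_config(n_patients = 3, duration_s = 600,
                                      seed = 7))
  expect_identical(ch$vitals[[1]], ch3$vitals[[1]])
  expect_identical(ch$doses[[2]], ch3$doses[[2]])
})

test_that("missing_rate zero produces complete frames", {
  ch <- generate_cohort(small_config(missing_rate = 0))
  for (v in ch$vitals) expect_false(anyNA(v))
})

test_that("signals respect physiologic clip bounds", {
  cfg <- small_config(n_patients = 3, duration_s = 1200, seed = 3,
                      missing_rate = 0)
  ch <- generate_cohort(cfg)
  for (v in ch$vitals) {
    for (s in vital_signals()) {
      b <- cfg$clip_bounds[[s]]
      expect_true(all(v[[s]] >= b[1] & v[[s]] <= b[2]))
    }
    expect_true(all(v$sao2 <= 100 & v$cnirs <= 100 & v$rnirs <= 100))
  }
})

test_that("profiles satisfy their invariants", {
  ch <- generate_cohort(small_config(n_patients = 20, seed = 5))
  p <- ch$profiles
  expect_true(all(p$age_years > 0 & p$weight_kg > 0 & p$height_cm > 0))
  expect_equal(p$bsa_m2, bsa_mosteller(p$height_cm, p$weight_kg),
               tolerance = 1e-9)
  expect_true(all(p$single_ventricle %in% 0:1))
  expect_true(all(p$critical_illness %in% 0:1))
  expect_true(all(p$hemoglobin_g_dl > 0))
})

test_that("dose schedules are piecewise-constant, bounded, and unit-aware", {
  cfg <- small_config(n_patients = 1, duration_s = 3600)
  # degenerate [0,0] range: all-zero series
  set.seed(1)
  expect_true(all(generate_dose_schedule("phenylephrine", cfg) == 0))
  # zero mean changes: constant series
  cfg0 <- small_config(duration_s = 3600,
                       dose_schedule = utils::modifyList(
                         default_dose_schedule(), list(mean_changes = 0)))
  set.seed(2)
  d <- generate_dose_schedule("milrinone", cfg0)
  expect_length(unique(d), 1)
  # bound check by exhaustive scan over many draws
  set.seed(3)
  cfg1 <- small_config(duration_s = 1000)
  draws <- unlist(lapply(1:40, function(i)
    generate_dose_schedule("epinephrine", cfg1)))
  expect_gte(length(draws), 1000)
  expect_true(all(draws >= 0 & draws <= 0.1))
  expect_error(generate_dose_schedule("dopamine", cfg), "known drugs")
})

test_that("effect model reproduces the stated mean curve exactly when noise is off", {
  base <- ref_baseline()
  n <- 120
  doses <- data.frame(time_s = 0:(n - 1))
  for (d in drug_names()) doses[[d]] <- 0
  doses$epinephrine <- rep(c(0, 0.05), each = n / 2)
  spec <- default_effect_spec()
  trend <- default_time_trend()
  noise0 <- default_noise()
  noise0$sd[] <- 0
  got <- apply_effect_model(base, doses, spec, trend, noise0)
  # independent evaluation of baseline + trend*t + delta*sat(dose)
  sat <- doses$epinephrine / (doses$epinephrine + spec$k_half[["epinephrine"]])
  for (s in vital_signals()) {
    expected <- base[[s]] + trend[[s]] * (doses$time_s / 3600) +
      spec$deltas["epinephrine", s] * sat
    expect_equal(got[[s]], expected, tolerance = 1e-12)
  }
  # zero magnitudes, zero trend, zero noise: identity
  spec0 <- spec; spec0$deltas[] <- 0
  trend0 <- trend; trend0[] <- 0
  got0 <- apply_effect_model(base, doses, spec0, trend0, noise0)
  for (s in vital_signals())
    expect_equal(got0[[s]], rep(base[[s]], n))
})

test_that("noise-off response is monotone in dose with the configured sign", {
  base <- ref_baseline()
  spec <- default_effect_spec()
  noise0 <- default_noise(); noise0$sd[] <- 0
  trend0 <- default_time_trend(); trend0[] <- 0
  dose_grid <- seq(0, 0.1, length.out = 50)
  doses <- data.frame(time_s = seq_along(dose_grid) - 1)
  for (d in drug_names()) doses[[d]] <- 0
  for (drg in c("epinephrine", "nitroprusside")) {
    dd <- doses; dd[[drg]] <- dose_grid
    got <- apply_effect_model(base, dd, spec, trend0, noise0)
    for (s in c("cvp", "map", "hr")) {
      sgn <- sign(spec$deltas[drg, s])
      if (sgn == 0) next
      expect_true(all(sgn * diff(got[[s]]) >= 0),
                  info = paste(drg, s))
    }
  }
})

test_that("missingness injection is MCAR at the requested rate, sparing time", {
  ch <- generate_cohort(small_config(missing_rate = 0))
  v <- ch$vitals[[1]]
  set.seed(99)
  out <- inject_missingness(v, 0.5)
  cells <- unlist(out[vital_signals()])
  frac <- mean(is.na(cells))
  # binomial 99% interval at 0.5 on >= 5400 cells
  expect_gt(frac, 0.47)
  expect_lt(frac, 0.53)
  expect_false(anyNA(out$time_s))
  expect_identical(inject_missingness(v, 0), v)
  expect_error(inject_missingness(v, 1), "missing_rate")
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(synth_config(2, duration_s = 100, sample_interval_s = 7),
               "duration_s")
  expect_error(synth_config(2, missing_rate = 1), "missing_rate")
  expect_error(synth_config(2, drugs = c("epinephrine", "dopamine")), "drugs")
  bad_noise <- default_noise(); bad_noise$phi["hr"] <- 1
  expect_error(synth_config(2, noise = bad_noise), "phi")
  bad_sched <- default_dose_schedule()
  bad_sched$ranges$milrinone <- c(-1, 1)
  expect_error(synth_config(2, dose_schedule = bad_sched), "milrinone")
})

test_that("the generator's encoded direction matrix matches the noise-free derivation", {
  prof <- ref_profile()
  base <- ref_baseline()
  spec <- default_effect_spec()
  ranges <- default_dose_schedule()$ranges
  eval_at <- function(deltas_row, s) {
    v <- base + deltas_row * s
    derive_all(prof, as.data.frame(c(list(time_s = 0), as.list(v))))
  }
  d0 <- eval_at(spec$deltas[1, ] * 0, 0)
  ref <- reference_directions()
  # neutral thresholds: well below every intended nonzero response, well
  # above every intended null response, per outcome
  thr <- c(mcfp = 0.1, rv = 0.01, svri = 10, ci = 0.03, coer = 4e-3,
           roer = 4e-3)
  for (drg in drug_names()) {
    s <- saturating_dose(max(ranges[[drg]]), spec$k_half[[drg]])
    d1 <- eval_at(spec$deltas[drg, ], s)
    delta <- unlist(d1[, outcome_names()]) - unlist(d0[, outcome_names()])
    enc <- ifelse(abs(delta) < thr, 0L, as.integer(sign(delta)))
    expect_equal(unname(enc), unname(ref[drg, ]), info = drg)
  }
})
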