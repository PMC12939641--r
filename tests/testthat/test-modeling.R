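test_that("train/test split is disjoint, exhaustive and seed-reproducible", {
  ft <- toy_feature_table(1000)
  ft$mcfp <- rnorm(1000)
  spec <- model_spec("mcfp", seed = 4)
  sp <- split_data(ft, spec)
  expect_equal(nrow(sp$train), 800)
  expect_equal(nrow(sp$test), 200)
  key <- function(df) sort(df$time_s)
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  expect_equal(sort(c(key(sp$train), key(sp$test))), sort(ft$time_s))
  sp2 <- split_data(ft, spec)
  expect_identical(sp, sp2)
  # grouped mode keeps whole patients on one side
  spg <- split_data(ft, spec, group_by_patient = TRUE)
  expect_length(intersect(unique(spg$train$patient_id),
                          unique(spg$test$patient_id)), 0)
  expect_error(split_data(ft[0, ], spec), "empty")
})

test_that("a noiseless linear signal is learned nearly perfectly", {
  ft <- toy_feature_table(10000, seed = 2)
  ft$mcfp <- 5 + 12 * ft$milrinone
  spec <- model_spec("mcfp", seed = 2)
  sp <- split_data(ft, spec)
  m <- fit_outcome_model(sp$train, sp$test, spec)
  expect_gte(m$r2, 0.95)
  # planted-signal recovery: the informative feature ranks first
  expect_equal(names(m$importance)[1], "milrinone")
  # determinism
  m2 <- fit_outcome_model(sp$train, sp$test, spec)
  expect_equal(m$r2, m2$r2)
  expect_equal(m$importance, m2$importance)
})

test_that("pure-noise targets yield near-zero held-out R2", {
  ft <- toy_feature_table(10000, seed = 3)
  set.seed(30)
  ft$rv <- rnorm(10000)
  spec <- model_spec("rv", seed = 3)
  sp <- split_data(ft, spec)
  m <- fit_outcome_model(sp$train, sp$test, spec)
  expect_lte(m$r2, 0.1)
  expect_gt(m$mae, 0)
})

test_that("constant targets give zero MAE and graceful importances", {
  ft <- toy_feature_table(500, seed = 5)
  ft$ci <- 3.2
  spec <- model_spec("ci", seed = 5)
  sp <- split_data(ft, spec)
  m <- fit_outcome_model(sp$train, sp$test, spec)
  expect_equal(m$mae, 0, tolerance = 1e-12)
  expect_equal(sum(m$importance), 1, tolerance = 1e-9)
  expect_true(all(m$importance >= 0))
})

test_that("non-finite targets are refused with offending rows named", {
  ft <- toy_feature_table(100, seed = 6)
  ft$svri <- rnorm(100)
  ft$svri[c(7, 9)] <- NA
  spec <- model_spec("svri", seed = 6)
  sp <- split_data(ft, spec)
  expect_error(fit_outcome_model(sp$train, sp$test, spec), "non-finite")
})

test_that("importance weights are normalized with alphabetical tie-break", {
  ft <- toy_feature_table(2000, seed = 7)
  ft$coer <- 0.2 + 0.1 * ft$vasopressin
  spec <- model_spec("coer", seed = 7)
  sp <- split_data(ft, spec)
  m <- fit_outcome_model(sp$train, sp$test, spec)
  w <- importance_ranking(m)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(diff(w) <= 0))
  ties <- which(duplicated(w) | duplicated(w, fromLast = TRUE))
  if (length(ties) > 1) {
    grp <- split(names(w)[ties], w[ties])
    for (g in grp) expect_identical(g, sort(g))
  }
})

test_that("partial dependence is flat for ignored drugs and tracks planted monotone signals", {
  ft <- toy_feature_table(4000, seed = 8)
  ft$roer <- 0.3 + 0.2 * ft$nitroprusside^2
  spec <- model_spec("roer", seed = 8)
  sp <- split_data(ft, spec)
  m <- fit_outcome_model(sp$train, sp$test, spec)
  pd_sig <- partial_dependence(m, "nitroprusside")
  expect_equal(nrow(pd_sig), 25)
  # monotone up to estimation noise: overall rise dominates local wiggle
  expect_gt(pd_sig$yhat[25] - pd_sig$yhat[1], 0.1)
  expect_true(all(diff(pd_sig$yhat) > -0.01))
  # drug the target ignores: flat relative to the signal scale
  pd_flat <- partial_dependence(m, "milrinone")
  expect_lt(max(pd_flat$yhat) - min(pd_flat$yhat), 0.02)
  # grid respects the observed range
  expect_gte(min(pd_sig$dose), min(ft$nitroprusside))
  expect_lte(max(pd_sig$dose), max(ft$nitroprusside))
  expect_error(partial_dependence(m, "nitroprusside", grid = c(-1, 2)),
               "outside the observed range")
  # single-point grid equals the mean prediction at that dose
  g0 <- stats::median(ft$nitroprusside)
  pd1 <- partial_dependence(m, "nitroprusside", grid = g0)
  bg <- sp$train[, spec$features]
  set.seed(spec$seed + 1L)
  bg <- bg[sample.int(nrow(bg), 1000), ]
  bg$nitroprusside <- g0
  expect_equal(pd1$yhat,
               mean(predict(m$fit, data = bg, num.threads = 1)$predictions),
               tolerance = 1e-9)
})

test_that("direction calls obey the neutral deadband rule", {
  flat <- structure(data.frame(dose = 0:4, yhat = rep(1, 5)),
                    class = c("pd_curve", "data.frame"))
  expect_equal(direction_of_effect(flat, outcome_sd = 2), "neutral")
  up <- flat; up$yhat <- c(0, 0.5, 1, 1.5, 2)
  expect_equal(direction_of_effect(up, outcome_sd = 2), "increase")
  down <- flat; down$yhat <- rev(up$yhat)
  expect_equal(direction_of_effect(down, outcome_sd = 2), "decrease")
  # a rise of exactly one SD beats any eps < 1
  one_sd <- flat; one_sd$yhat <- c(0, 0, 0, 0, 2)
  expect_equal(direction_of_effect(one_sd, outcome_sd = 2), "increase")
  # inside the band: neutral
  tiny <- flat; tiny$yhat <- c(0, 0, 0, 0, 0.05)
  expect_equal(direction_of_effect(tiny, outcome_sd = 2), "neutral")
  expect_error(direction_of_effect(flat[1, ], 1), "two points")
})

test_that("shuffling an informative feature degrades its importance rank", {
  worse <- 0L
  for (s in 1:5) {
    ft <- toy_feature_table(2000, seed = 100 + s)
    ft$mcfp <- 10 + 3 * ft$norepinephrine + rnorm(2000, 0, 0.5)
    spec <- model_spec("mcfp", seed = 100 + s)
    sp <- split_data(ft, spec)
    m <- fit_outcome_model(sp$train, sp$test, spec)
    rank_before <- which(names(m$importance) == "norepinephrine")
    set.seed(200 + s)
    ft$norepinephrine <- sample(ft$norepinephrine)
    sp2 <- split_data(ft, spec)
    m2 <- fit_outcome_model(sp2$train, sp2$test, spec)
    rank_after <- which(names(m2$importance) == "norepinephrine")
    if (rank_after > rank_before) worse <- worse + 1L
  }
  expect_gte(worse, 4)
})

test_that("run_all_outcomes returns six results with coherent artifacts", {
  ft <- toy_feature_table(1500, seed = 9)
  set.seed(90)
  ft$mcfp <- 10 + 2 * ft$vasopressin + rnorm(1500, 0, 0.2)
  ft$rv <- 1 + 0.5 * ft$vasopressin + rnorm(1500, 0, 0.05)
  ft$svri <- 1400 - 300 * ft$milrinone + rnorm(1500, 0, 30)
  ft$ci <- 2.5 + 0.5 * ft$nitroprusside + rnorm(1500, 0, 0.1)
  ft$coer <- 0.25 + 0.05 * ft$norepinephrine + rnorm(1500, 0, 0.01)
  ft$roer <- 0.3 - 0.05 * ft$epinephrine + rnorm(1500, 0, 0.01)
  res <- run_all_outcomes(ft, seed = 9)
  expect_named(res, outcome_names())
  for (r in res) {
    expect_true(all(r$directions %in% c("increase", "decrease", "neutral")))
    expect_equal(sum(r$importance), 1, tolerance = 1e-9)
    expect_gte(r$mae, 0)
  }
  # the never-dosed column yields a flat single-point curve and neutral call
  expect_equal(nrow(res$mcfp$pd_curves$phenylephrine), 1)
  expect_equal(unname(res$mcfp$directions["phenylephrine"]), "neutral")
  # planted signs recovered on clean data
  expect_equal(unname(res$mcfp$directions["vasopressin"]), "increase")
  expect_equal(unname(res$svri$directions["milrinone"]), "decrease")
  expect_error(run_all_outcomes(ft[, setdiff(names(ft), "rv")]),
               "lacks outcome")
})
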