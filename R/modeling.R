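#' Random-forest model specification
#'
#' One forest per derived outcome: 100 trees, minimum leaf size 2, bootstrap
#' sampling, all features considered at every split, fitted on a random
#' 80:20 train/test row split.
#'
#' @param outcome one of [outcome_names()]
#' @param n_trees number of trees (default 100)
#' @param min_leaf minimum terminal node size (default 2)
#' @param bootstrap bootstrap-sample each tree (default TRUE)
#' @param split_fraction training share in (0, 1) (default 0.8)
#' @param seed integer seed controlling the split and the forest
#' @param features predictor columns (default [feature_names()])
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(outcome, n_trees = 100, min_leaf = 2,
                       bootstrap = TRUE, split_fraction = 0.8, seed = 1L,
                       features = feature_names()) {
  if (!outcome %in% outcome_names())
    stop("outcome must be one of: ", paste(outcome_names(), collapse = ", "),
         call. = FALSE)
  check_scalar_num(n_trees, "n_trees", lower = 1)
  check_scalar_num(min_leaf, "min_leaf", lower = 1)
  check_scalar_num(split_fraction, "split_fraction", lower = 0, upper = 1,
                   strict_lower = TRUE)
  if (split_fraction >= 1) stop_config("split_fraction", "must be < 1")
  structure(list(outcome = outcome, n_trees = as.integer(n_trees),
                 min_leaf = as.integer(min_leaf), bootstrap = isTRUE(bootstrap),
                 split_fraction = split_fraction, seed = as.integer(seed),
                 features = features),
            class = "model_spec")
}

#' Split a feature table into train and test rows
#'
#' Random row-level split at the specification's fraction, reproducible by
#' seed; disjoint and exhaustive. With `group_by_patient = TRUE` whole
#' patients are assigned to one side (a guard against the optimistic bias of
#' row-splitting autocorrelated series).
#'
#' @param table feature table
#' @param spec a [model_spec()]
#' @param group_by_patient split at the patient level instead of row level
#' @return List with `train` and `test` data frames.
#' @export
split_data <- function(table, spec, group_by_patient = FALSE) {
  if (nrow(table) == 0L) stop("feature table is empty", call. = FALSE)
  set.seed(spec$seed)
  if (group_by_patient) {
    pats <- unique(table$patient_id)
    n_tr <- max(1L, floor(spec$split_fraction * length(pats)))
    tr_p <- sample(pats, n_tr)
    idx <- table$patient_id %in% tr_p
  } else {
    n_tr <- floor(spec$split_fraction * nrow(table))
    tr <- sample.int(nrow(table), n_tr)
    idx <- logical(nrow(table))
    idx[tr] <- TRUE
  }
  list(train = table[idx, , drop = FALSE],
       test = table[!idx, , drop = FALSE])
}

#' Fit one outcome's random-forest regression
#'
#' Fits a forest with the specified hyperparameters on the training rows and
#' evaluates held-out R-squared and mean absolute error on the test rows.
#' Deterministic given the seed (single-threaded).
#'
#' @param train,test train/test splits from [split_data()]
#' @param spec a [model_spec()]
#' @return Object of class `outcome_model`: `outcome`, `fit` (ranger
#'   object), `r2`, `mae`, `importance` (normalized, descending),
#'   `outcome_sd` (training-set SD used for the neutral band), `train`
#'   (kept for partial dependence), `spec`.
#' @export
fit_outcome_model <- function(train, test, spec) {
  y <- train[[spec$outcome]]
  if (is.null(y)) stop("outcome column '", spec$outcome, "' not found",
                       call. = FALSE)
  bad <- which(!is.finite(y))
  if (length(bad))
    stop("non-finite '", spec$outcome, "' target in training rows: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  bad_te <- which(!is.finite(test[[spec$outcome]]))
  if (length(bad_te))
    stop("non-finite '", spec$outcome, "' target in test rows: ",
         paste(utils::head(bad_te, 5), collapse = ", "),
         if (length(bad_te) > 5) " ..." else "", call. = FALSE)
  dat <- train[, c(spec$features, spec$outcome), drop = FALSE]
  fit <- ranger::ranger(
    formula = stats::as.formula(paste(spec$outcome, "~ .")),
    data = dat,
    num.trees = spec$n_trees,
    min.node.size = spec$min_leaf,
    mtry = length(spec$features),
    replace = spec$bootstrap,
    sample.fraction = if (spec$bootstrap) 1 else 0.632,
    importance = "impurity",
    seed = spec$seed,
    num.threads = 1,
    verbose = FALSE
  )
  pred <- stats::predict(fit, data = test[, spec$features, drop = FALSE],
                         num.threads = 1)$predictions
  obs <- test[[spec$outcome]]
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot == 0) ifelse(ss_res == 0, 1, 0) else 1 - ss_res / ss_tot
  mae <- mean(abs(obs - pred))
  structure(list(outcome = spec$outcome, fit = fit, r2 = r2, mae = mae,
                 importance = importance_ranking(fit),
                 outcome_sd = stats::sd(y), train = train, spec = spec),
            class = "outcome_model")
}

#' @export
print.outcome_model <- function(x, ...) {
  cat(sprintf("outcome model [%s]: held-out R2 = %.3f, MAE = %.4g\n",
              x$outcome, x$r2, x$mae))
  cat("top features:",
      paste(utils::head(names(x$importance), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Normalized impurity-based feature importance ranking
#'
#' Impurity importances normalized to sum to one and sorted in descending
#' order, ties broken alphabetically by feature name. When no split was ever
#' made (all-constant features) the weights are uniform, alphabetical.
#'
#' @param model a fitted ranger forest or an `outcome_model`
#' @return Named numeric vector of weights summing to 1.
#' @export
importance_ranking <- function(model) {
  if (inherits(model, "outcome_model")) model <- model$fit
  imp <- tryCatch(ranger::importance(model),
                  error = function(e) stop("model has no importance scores; ",
                                           "was it fitted with impurity ",
                                           "importance?", call. = FALSE))
  imp <- pmax(imp, 0)
  if (sum(imp) == 0) imp[] <- 1
  w <- imp / sum(imp)
  w[order(-w, names(w))]
}

#' Partial dependence of the model on one drug's dose
#'
#' Standard partial dependence: for each grid dose, set every background
#' row's dose of the drug to that value, predict, and average. The default
#' grid is 25 evenly spaced points between the 1st and 99th percentile of
#' the observed (zero-inclusive) dose; a zero-variance dose column yields a
#' single-point (flat) curve. Background rows are the training rows,
#' deterministically subsampled to at most `max_background`.
#'
#' @param model an `outcome_model`
#' @param drug feature name to sweep
#' @param grid optional explicit dose grid (must lie within the observed
#'   range)
#' @param n_grid grid size (default 25)
#' @param max_background background subsample cap (default 1000)
#' @return Data frame with columns `dose` and `yhat`, class `pd_curve`.
#' @export
partial_dependence <- function(model, drug, grid = NULL, n_grid = 25,
                               max_background = 1000) {
  if (!drug %in% model$spec$features)
    stop("'", drug, "' is not a model feature", call. = FALSE)
  x <- model$train[[drug]]
  lo <- stats::quantile(x, 0.01, names = FALSE)
  hi <- stats::quantile(x, 0.99, names = FALSE)
  if (is.null(grid)) {
    grid <- if (hi > lo) seq(lo, hi, length.out = n_grid) else lo
  } else {
    if (min(grid) < min(x) || max(grid) > max(x))
      stop("grid extends outside the observed range of '", drug, "'",
           call. = FALSE)
  }
  bg <- model$train[, model$spec$features, drop = FALSE]
  if (nrow(bg) > max_background) {
    set.seed(model$spec$seed + 1L)
    bg <- bg[sample.int(nrow(bg), max_background), , drop = FALSE]
  }
  # one stacked prediction call: grid values block-repeated over background
  stacked <- bg[rep(seq_len(nrow(bg)), times = length(grid)), , drop = FALSE]
  stacked[[drug]] <- rep(grid, each = nrow(bg))
  pred <- stats::predict(model$fit, data = stacked,
                         num.threads = 1)$predictions
  yhat <- colMeans(matrix(pred, nrow = nrow(bg)))
  structure(data.frame(dose = grid, yhat = yhat),
            class = c("pd_curve", "data.frame"))
}

#' Direction-of-effect call from a partial-dependence curve
#'
#' Compares the partial dependence at the top of the dose grid with the
#' bottom: `increase` if the rise exceeds `eps` outcome standard deviations,
#' `decrease` if the fall does, otherwise `neutral` (the deadband that
#' produces blank cells in the direction matrix).
#'
#' @param pd a `pd_curve` with at least two points
#' @param outcome_sd standard deviation of the outcome (training set)
#' @param eps neutral-band width in outcome SDs (default 0.05)
#' @return One of `"increase"`, `"decrease"`, `"neutral"`.
#' @export
direction_of_effect <- function(pd, outcome_sd, eps = 0.05) {
  if (nrow(pd) < 2L)
    stop("partial-dependence curve needs at least two points", call. = FALSE)
  delta <- pd$yhat[nrow(pd)] - pd$yhat[1L]
  band <- eps * outcome_sd
  if (delta > band) "increase" else if (delta < -band) "decrease" else "neutral"
}

#' Fit all six outcome models and extract the reporting artifacts
#'
#' Runs the full per-outcome analysis: split, forest fit, held-out R-squared
#' and MAE, normalized importance ranking, per-drug partial-dependence
#' curves, and direction-of-effect calls. Drugs whose observed dose is
#' constant (e.g. a never-dosed column) get a flat single-point curve and a
#' `neutral` call.
#'
#' @param table feature table from [build_feature_table()]
#' @param seed seed shared by every outcome's split and forest
#' @param outcomes outcome subset (default all six)
#' @param drugs drugs to profile (default all eight)
#' @param eps neutral-band width for [direction_of_effect()]
#' @param group_by_patient forwarded to [split_data()]
#' @param ... forwarded to [model_spec()] (n_trees, min_leaf, ...)
#' @return Named list of `model_result` objects, one per outcome, each with
#'   `outcome`, `r2`, `mae`, `importance`, `pd_curves`, `directions`,
#'   `outcome_sd`.
#' @export
run_all_outcomes <- function(table, seed = 1L, outcomes = outcome_names(),
                             drugs = drug_names(), eps = 0.05,
                             group_by_patient = FALSE, ...) {
  miss <- setdiff(outcomes, names(table))
  if (length(miss))
    stop("feature table lacks outcome column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  results <- lapply(outcomes, function(oc) {
    spec <- model_spec(oc, seed = seed, ...)
    sp <- split_data(table, spec, group_by_patient = group_by_patient)
    m <- fit_outcome_model(sp$train, sp$test, spec)
    pd_curves <- list()
    directions <- character(0)
    for (d in drugs) {
      pd <- partial_dependence(m, d)
      pd_curves[[d]] <- pd
      directions[[d]] <- if (nrow(pd) < 2L) "neutral"
                         else direction_of_effect(pd, m$outcome_sd, eps = eps)
    }
    structure(list(outcome = oc, r2 = m$r2, mae = m$mae,
                   importance = m$importance, pd_curves = pd_curves,
                   directions = directions, outcome_sd = m$outcome_sd,
                   model = m),
              class = "model_result")
    })
  names(results) <- outcomes
  results
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("model result [%s]: R2 = %.3f, MAE = %.4g\n",
              x$outcome, x$r2, x$mae))
  arrows <- c(increase = "up", decrease = "down", neutral = "-")
  cat("directions:",
      paste(names(x$directions), arrows[x$directions], collapse = ", "),
      "\n")
  invisible(x)
}
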