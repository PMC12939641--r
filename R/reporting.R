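#' Pipeline run configuration
#'
#' Bundles everything one reproducible end-to-end run needs. Exactly one of
#' `synthetic` (a [synth_config()] or argument list for it) and `real_data`
#' (paths to exported tabular files) must be supplied.
#'
#' @param synthetic a [synth_config()] or a list of arguments for it
#' @param real_data list with `vitals_dir` (one CSV per patient: `time_s`
#'   plus [vital_signals()]), `doses_dir` (one event CSV per patient:
#'   `time_s`, `drug`, `dose`, optional `unit`) and `manifest` (YAML/JSON
#'   file with a `patients` list of profile fields, optional `admission_s`)
#' @param constants physiologic constants: `hemoglobin_g_dl` default used
#'   when a profile lacks one, `k_o2`, `vo2_indexed`, `vr_flow`
#' @param model list of [model_spec()] overrides (`n_trees`, `min_leaf`,
#'   `split_fraction`, `eps`, `group_by_patient`)
#' @param seed global seed; per-stage seeds are derived by fixed offsets
#' @return Object of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, real_data = NULL,
                       constants = list(), model = list(), seed = 1L) {
  if (is.null(synthetic) == is.null(real_data))
    stop("exactly one of `synthetic` and `real_data` must be supplied",
         call. = FALSE)
  if (!is.null(synthetic) && !inherits(synthetic, "synth_config")) {
    synthetic$seed <- synthetic$seed %||% seed
    synthetic <- do.call(synth_config, synthetic)
  }
  if (!is.null(real_data)) {
    for (f in c("vitals_dir", "doses_dir", "manifest"))
      if (is.null(real_data[[f]]))
        stop_config(paste0("real_data$", f), "is required")
  }
  constants <- utils::modifyList(
    list(hemoglobin_g_dl = 13, k_o2 = 1.36, vo2_indexed = TRUE,
         vr_flow = "co"), constants)
  model <- utils::modifyList(
    list(n_trees = 100, min_leaf = 2, split_fraction = 0.8, eps = 0.05,
         group_by_patient = FALSE), model)
  structure(list(synthetic = synthetic, real_data = real_data,
                 constants = constants, model = model,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with top-level blocks `synthetic` or `real_data`,
#'   plus optional `constants`, `model`, `seed`
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(synthetic = y$synthetic, real_data = y$real_data,
             constants = y$constants %||% list(),
             model = y$model %||% list(), seed = y$seed %||% 1L)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Write a cohort to a directory of per-patient CSV files
#'
#' Layout: `vitals/<patient>.csv`, `doses/<patient>.csv`, and
#' `manifest.json` (profiles plus a config echo).
#'
#' @param cohort a `synth_cohort`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "vitals"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "doses"), recursive = TRUE, showWarnings = FALSE)
  for (pid in cohort$profiles$patient_id) {
    data.table::fwrite(cohort$vitals[[pid]],
                       file.path(dir, "vitals", paste0(pid, ".csv")))
    data.table::fwrite(cohort$doses[[pid]],
                       file.path(dir, "doses", paste0(pid, ".csv")))
  }
  manifest <- list(profiles = cohort$profiles,
                   config = config_echo(cohort$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# flatten a synth_config into plain lists for serialization
config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$effect_spec <- list(
    deltas = as.data.frame(cfg$effect_spec$deltas),
    k_half = as.list(cfg$effect_spec$k_half))
  cfg
}

read_real_cohort <- function(real_data, window_s = WINDOW_S) {
  man_path <- real_data$manifest
  if (!file.exists(man_path))
    stop("manifest file not found: ", man_path, call. = FALSE)
  man <- if (grepl("\\.json$", man_path)) jsonlite::read_json(man_path)
         else yaml::read_yaml(man_path)
  pats <- man$patients %||% man$profiles
  if (is.null(pats)) stop("manifest lacks a `patients` block", call. = FALSE)
  profiles <- do.call(rbind, lapply(pats, function(p) {
    data.frame(patient_id = p$patient_id,
               age_years = p$age_years, weight_kg = p$weight_kg,
               height_cm = p$height_cm %||% NA_real_,
               bsa_m2 = p$bsa_m2 %||%
                 bsa_mosteller(p$height_cm, p$weight_kg),
               single_ventricle = p$single_ventricle %||% 0L,
               critical_illness = p$critical_illness %||% 1L,
               hemoglobin_g_dl = p$hemoglobin_g_dl %||% NA_real_,
               admission_s = p$admission_s %||% 0)
  }))
  vitals <- list(); doses <- list()
  for (i in seq_len(nrow(profiles))) {
    pid <- profiles$patient_id[i]
    vf <- file.path(real_data$vitals_dir, paste0(pid, ".csv"))
    df <- file.path(real_data$doses_dir, paste0(pid, ".csv"))
    if (!file.exists(vf)) stop("vitals file not found: ", vf, call. = FALSE)
    if (!file.exists(df)) stop("dose file not found: ", df, call. = FALSE)
    v <- as.data.frame(data.table::fread(vf))
    rel <- normalize_time(v$time_s, profiles$admission_s[i],
                          window_s = window_s)
    keep <- floor(v$time_s - profiles$admission_s[i])
    v <- v[keep >= 0 & keep < window_s, , drop = FALSE]
    v$time_s <- rel
    ev <- as.data.frame(data.table::fread(df))
    if (nrow(ev)) ev$time_s <- ev$time_s - profiles$admission_s[i]
    d <- collate_doses(ev[ev$time_s >= 0 | !nrow(ev), , drop = FALSE],
                       grid = v$time_s)
    vitals[[pid]] <- v
    doses[[pid]] <- d
  }
  list(profiles = profiles, vitals = vitals, doses = doses)
}

#' Run the full pipeline into an output directory
#'
#' Orchestrates cohort generation (or real-data ingestion), imputation,
#' hemodynamic derivation, feature assembly, the six outcome models, and
#' report rendering, writing every artifact plus a log into `out_dir`.
#' Deterministic given the configuration's global seed. A failing stage
#' aborts with an error naming the stage; artifacts written before the
#' failure are preserved.
#'
#' @param config a [run_config()] (or path to a YAML file for one)
#' @param out_dir output directory
#' @param figures also render Guyton-diagram PNG figures (default TRUE;
#'   curve CSVs are always written)
#' @return Invisibly, a list with `features`, `results`, `tables`,
#'   `diagrams`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, figures = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  note("venotone %s | global seed %d",
       as.character(utils::packageVersion("venotone")), config$seed)

  cohort <- with_stage("synth", {
    if (!is.null(config$synthetic)) {
      ch <- generate_cohort(config$synthetic)
      write_cohort(ch, file.path(out_dir, "cohort"))
      ch
    } else {
      read_real_cohort(config$real_data)
    }
  })
  note("synth: %d patients, %d rows each", nrow(cohort$profiles),
       nrow(cohort$vitals[[1]]))

  imputed <- with_stage("prep", {
    lapply(cohort$vitals, impute_patient_median)
  })
  n_fully <- sum(lengths(lapply(imputed, attr, "fully_missing")))
  note("prep: imputed patient medians; %d fully-missing signal(s) flagged",
       n_fully)

  cst <- config$constants
  derived <- with_stage("derive", {
    out <- list()
    for (i in seq_len(nrow(cohort$profiles))) {
      prof <- cohort$profiles[i, ]
      if (is.na(prof$hemoglobin_g_dl %||% NA))
        prof$hemoglobin_g_dl <- cst$hemoglobin_g_dl
      out[[prof$patient_id]] <-
        derive_all(prof, imputed[[prof$patient_id]], k_o2 = cst$k_o2,
                   vo2_indexed = cst$vo2_indexed, vr_flow = cst$vr_flow)
    }
    out
  })

  features <- with_stage("features", {
    ft <- build_feature_table(cohort$profiles, cohort$doses, derived)
    data.table::fwrite(ft, file.path(out_dir, "features.csv"))
    ft
  })
  note("features: %d rows (%d dropped as undefined)", nrow(features),
       attr(features, "n_dropped"))

  mdl <- config$model
  results <- with_stage("model", {
    run_all_outcomes(features, seed = config$seed + 1000L,
                     eps = mdl$eps, n_trees = mdl$n_trees,
                     min_leaf = mdl$min_leaf,
                     split_fraction = mdl$split_fraction,
                     group_by_patient = mdl$group_by_patient)
  })
  for (oc in names(results)) {
    r <- results[[oc]]
    note("model [%s]: held-out R2 %.3f, MAE %.4g", oc, r$r2, r$mae)
    jsonlite::write_json(
      list(outcome = oc, r2 = r$r2, mae = r$mae,
           importance = as.list(r$importance),
           directions = as.list(r$directions)),
      file.path(out_dir, paste0("model_", oc, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    pd_all <- do.call(rbind, lapply(names(r$pd_curves), function(d)
      cbind(drug = d, as.data.frame(r$pd_curves[[d]]))))
    data.table::fwrite(pd_all, file.path(out_dir, paste0("pd_", oc, ".csv")))
  }

  tables <- with_stage("report", {
    tb <- render_tables(results)
    data.table::fwrite(tb$ranking, file.path(out_dir, "table_importance.csv"))
    data.table::fwrite(tb$direction, file.path(out_dir, "table_direction.csv"))
    writeLines(tb$ranking_md, file.path(out_dir, "table_importance.md"))
    writeLines(tb$direction_md, file.path(out_dir, "table_direction.md"))
    tb
  })

  diagrams <- with_stage("diagrams", {
    figure_drugs <- c("epinephrine", "norepinephrine", "milrinone",
                      "vasopressin", "calcium_chloride")
    if (!is.null(config$synthetic))
      figure_drugs <- intersect(figure_drugs, config$synthetic$drugs)
    dg <- lapply(figure_drugs, function(d)
      drug_guyton_pair(cohort, derived, d,
                       synth_cfg = config$synthetic))
    names(dg) <- figure_drugs
    for (d in figure_drugs) {
      pair <- dg[[d]]
      curves <- rbind(as.data.frame(pair$baseline), as.data.frame(pair$on))
      data.table::fwrite(curves, file.path(out_dir,
                                           paste0("guyton_", d, ".csv")))
      if (figures) {
        ok <- tryCatch({
          p <- plot(pair$baseline, pair$on)
          ggplot2::ggsave(file.path(out_dir, paste0("guyton_", d, ".png")),
                          p, width = 6, height = 4, dpi = 120)
          TRUE
        }, error = function(e) FALSE)
        if (!ok) note("diagrams: PNG rendering unavailable for %s", d)
      }
    }
    dg
  })

  jsonlite::write_json(
    list(seed = config$seed, constants = cst, model = mdl,
         synthetic = if (!is.null(config$synthetic))
           config_echo(config$synthetic),
         real_data = config$real_data),
    file.path(out_dir, "run_config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(features = features, results = results, tables = tables,
                 diagrams = diagrams, out_dir = out_dir))
}

# baseline vs drug-on venous-return diagrams for one drug, anchored at the
# cohort's median operating state
drug_guyton_pair <- function(cohort, derived, drug, synth_cfg = NULL) {
  med <- function(col, frames) stats::median(
    unlist(lapply(frames, function(f) f[[col]])), na.rm = TRUE)
  mcfp0 <- med("mcfp", derived)
  rv0 <- med("rv", derived)
  co0 <- med("co", derived)
  cc <- list(f_max = 2 * co0, rap0 = -4, tau = 4)
  base_dg <- guyton_diagram(mcfp0, rv0, cc, condition_label = "baseline")
  spec <- if (!is.null(synth_cfg)) synth_cfg$effect_spec
          else default_effect_spec()
  ranges <- if (!is.null(synth_cfg)) synth_cfg$dose_schedule$ranges
            else default_dose_schedule()$ranges
  s <- saturating_dose(max(ranges[[drug]]), spec$k_half[[drug]])
  d_cvp <- spec$deltas[drug, "cvp"] * s
  d_map <- spec$deltas[drug, "map"] * s
  d_rnirs <- spec$deltas[drug, "rnirs"] * s
  cvp0 <- med("cvp", cohort$vitals); map0 <- med("map", cohort$vitals)
  sao20 <- med("sao2", cohort$vitals); rnirs0 <- med("rnirs", cohort$vitals)
  # re-derive the drug-on operating state from shifted raw medians,
  # scaling CO by the Fick a-v difference ratio
  av0 <- (sao20 - rnirs0) / 100
  av1 <- (sao20 - (rnirs0 + d_rnirs)) / 100
  co1 <- co0 * av0 / av1
  cvp1 <- cvp0 + d_cvp; map1 <- map0 + d_map
  mcfp1 <- mcfp(cvp1, map1, co1)
  rv1 <- venous_resistance(mcfp1, cvp1, co1)
  on_dg <- guyton_diagram(mcfp1, rv1, cc,
                          condition_label = paste(drug, "on"))
  list(baseline = base_dg, on = on_dg)
}

#' Render study-style importance and direction matrices
#'
#' Produces the two reporting matrices: a feature-importance ranking matrix
#' (8 canonical rows -- relative time plus the seven dosed vasoactives --
#' by 6 outcome columns, most important at the top) and a direction-of-effect
#' matrix (7 drug rows by 6 outcome columns with up-arrow / down-arrow /
#' blank cells), each as a data frame and as Markdown.
#'
#' @param results named list of `model_result`s for all six outcomes
#' @return List: `ranking`, `direction` (data frames), `ranking_md`,
#'   `direction_md` (character vectors of Markdown lines).
#' @export
render_tables <- function(results) {
  if (length(results) < 6L)
    stop("render_tables needs all six outcome results, got ",
         length(results), call. = FALSE)
  canon <- c("time_s", setdiff(drug_names(), "phenylephrine"))
  pretty <- c(time_s = "Time", epinephrine = "Epinephrine",
              norepinephrine = "Norepinephrine", milrinone = "Milrinone",
              vasopressin = "Vasopressin",
              calcium_chloride = "Calcium chloride",
              nitroprusside = "Nitroprusside", nicardipine = "Nicardipine")
  outcomes <- names(results)
  ranking <- data.frame(rank = seq_along(canon))
  for (oc in outcomes) {
    w <- results[[oc]]$importance
    w <- w[names(w) %in% canon]
    w <- w[order(-w, names(w))]
    ranking[[oc]] <- pretty[names(w)]
  }
  arrows <- c(increase = "↑", decrease = "↓", neutral = "")
  drugs <- setdiff(drug_names(), "phenylephrine")
  direction <- data.frame(drug = pretty[drugs])
  for (oc in outcomes)
    direction[[oc]] <- unname(arrows[results[[oc]]$directions[drugs]])
  md_table <- function(df) {
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r)
      paste0("| ", paste(r, collapse = " | "), " |"))
    c(hdr, sep, rows)
  }
  list(ranking = ranking, direction = direction,
       ranking_md = md_table(ranking), direction_md = md_table(direction))
}
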