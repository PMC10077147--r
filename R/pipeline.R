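#' End-to-end pipeline configuration
#'
#' One master seed governs every child stream ([child_seed()]).  The
#' default imputation battery is the 13-dataset design: 10 chained-equation
#' chains plus one dataset each from KNN, SoftImpute and IterativeSVD.
#'
#' @param gen a [cohort_gen_config()] (synthetic source; its `seed` is
#'   overridden by `seed`).
#' @param frac_relaxed_only fraction of subjects emitted without procedure
#'   codes (relaxed-cohort-only; dropped again by the restriction step).
#' @param cohort a strict-mode [cohort_spec()].
#' @param imputation list of [imputation_config()]s.
#' @param alpha significance level of the evaluation grid.
#' @param resample a [resample_config()].
#' @param classifier a [classifier_config()].
#' @param cv a [cv_config()].
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(gen = cohort_gen_config(),
                            frac_relaxed_only = 0.08,
                            cohort = cohort_spec(),
                            imputation = list(
                              imputation_config("mice", m = 10L),
                              imputation_config("knn"),
                              imputation_config("soft_impute"),
                              imputation_config("iterative_svd")),
                            alpha = 0.05,
                            resample = resample_config(),
                            classifier = classifier_config(),
                            cv = cv_config(),
                            seed = 1L) {
  stopifnot(inherits(gen, "cohort_gen_config"),
            inherits(cohort, "cohort_spec"),
            all(vapply(imputation, inherits, TRUE, "imputation_config")))
  gen$seed <- as.integer(seed)
  for (i in seq_along(imputation))
    imputation[[i]]$seed <- child_seed(seed, "impute", i)
  resample$seed <- child_seed(seed, "rebalance")
  cv$seed <- child_seed(seed, "cv")
  structure(list(gen = gen, frac_relaxed_only = frac_relaxed_only,
                 cohort = cohort, imputation = imputation, alpha = alpha,
                 resample = resample, classifier = classifier, cv = cv,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

fnv1a <- function(raw) {
  # simple 31-bit polynomial rolling hash (fingerprinting only, not crypto);
  # kept in double precision so no integer overflow
  h <- 17
  for (b in as.integer(raw)) h <- (h * 131 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

hash_file <- function(path) fnv1a(readBin(path, "raw", file.size(path)))

config_fingerprint <- function(config) {
  sanitize <- function(x) {
    if (is.function(x)) return("<function>")
    if (is.list(x)) return(lapply(x, sanitize))
    x
  }
  fnv1a(charToRaw(as.character(
    jsonlite::toJSON(sanitize(unclass(config)), auto_unbox = TRUE,
                     digits = NA, force = TRUE))))
}

#' Run the full pipeline
#'
#' simulate -> cohort selection -> clean -> MCAR mask -> impute (all
#' configured engines) -> evaluate -> post-imputation restriction (strict
#' cohort, model variables only, derived shock index) -> rebalance + train
#' with repeated stratified CV -> reports.  All intermediate artifacts are
#' plain CSV/JSON under `out_dir`; the manifest records the config
#' fingerprint, seeds and per-stage row counts, making a run replayable.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created).
#' @return (invisibly) list with the key in-memory objects: `fm_masked`,
#'   `groups`, `labels`, `imputations`, `eval_report`, `cv_report`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage_log <- list()
  note <- function(stage, ...) {
    stage_log[[stage]] <<- list(...)
    message(sprintf("[%s] %s", stage,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = " ")))
  }

  # --- simulate ------------------------------------------------------------
  sim <- generate_event_table(config$gen,
                              frac_relaxed_only = config$frac_relaxed_only)
  write_event_tables(sim, out_dir)
  note("simulate", events = nrow(sim$events), coded = nrow(sim$coded))

  # --- cohort selection ----------------------------------------------------
  strict <- select_cohort(sim$coded, sim$coded, config$cohort)
  relaxed_spec <- config$cohort; relaxed_spec$mode <- "relaxed"
  relaxed <- select_cohort(sim$coded, sim$coded, relaxed_spec)
  data.table::fwrite(strict, file.path(out_dir, "cohort_strict.csv"))
  data.table::fwrite(relaxed, file.path(out_dir, "cohort_relaxed.csv"))
  note("cohort",
       strict_patients = sum(strict$group == "patient"),
       strict_controls = sum(strict$group == "control"),
       relaxed_included = sum(relaxed$group != "excluded"))

  # --- clean ---------------------------------------------------------------
  clusters <- default_clusters(config$gen$variables)
  cl <- clean_events(sim$events, clusters)
  writeLines(cl$log, file.path(out_dir, "cleaning_log.txt"))
  fm <- cl$fm
  keep <- fm$subject_id %in% relaxed$subject_id[relaxed$group != "excluded"]
  fm <- fm_subset(fm, rows = which(keep))
  rates <- vapply(config$gen$variables, `[[`, 0, "missing_rate")
  fm_masked <- apply_mcar(fm, rates, seed = config$seed)
  write_feature_matrix(fm_masked, file.path(out_dir, "feature_matrix.csv"))
  prof <- missingness_profile(fm_masked)
  data.table::fwrite(data.frame(variable = names(prof$per_variable),
                                missing_fraction = prof$per_variable),
                     file.path(out_dir, "missingness.csv"))
  note("clean", rows = nrow(fm_masked$data), vars = ncol(fm_masked$data),
       overall_missing = round(prof$overall, 4), repairs = length(cl$log))

  # --- impute --------------------------------------------------------------
  imp_dir <- file.path(out_dir, "imputed")
  sets <- list()
  for (cfg in config$imputation) {
    iset <- impute(fm_masked, cfg)
    write_imputation_set(iset, imp_dir)
    sets[[cfg$method]] <- iset
  }
  n_datasets <- sum(vapply(sets, function(s) length(s$completed), 0L))
  note("impute", engines = length(sets), datasets = n_datasets)

  # --- evaluate ------------------------------------------------------------
  ev <- evaluate_imputation_set(fm_masked, sets, alpha = config$alpha)
  write_eval_report(ev, file.path(out_dir, "eval"))
  note("evaluate", tests = nrow(ev$results),
       significant = sum(ev$results$significant))

  # --- restriction: final cohort + model variables + derived shock index ---
  final_ids <- strict$subject_id[strict$group %in% c("patient", "control")]
  rows <- which(fm_masked$subject_id %in% final_ids)
  labels <- as.integer(strict$group[match(fm_masked$subject_id[rows],
                                          strict$subject_id)] == "patient")
  model_vars <- names(config$gen$variables)[
    !vapply(config$gen$variables, `[[`, TRUE, "imputation_only")]
  restrict <- function(cfm) {
    r <- fm_subset(cfm, rows = rows, vars = model_vars)
    if (all(c("heart_rate", "systolic_bp") %in% model_vars)) {
      r$data$shock_index <- shock_index(r$data$heart_rate, r$data$systolic_bp)
      r$meta <- rbind(r$meta, data.frame(name = "shock_index",
                                         type = "continuous", unit = "",
                                         levels = NA_character_))
    }
    r
  }
  mice_sets <- sets[["mice"]]
  if (is.null(mice_sets)) mice_sets <- sets[[1]]
  restricted <- lapply(mice_sets$completed, restrict)
  names(restricted) <- sprintf("%s_%d", mice_sets$method,
                               seq_along(restricted))
  write_feature_matrix(restricted[[1]],
                       file.path(out_dir, "final_dataset_1.csv"))
  note("restrict", rows = length(rows), vars = ncol(restricted[[1]]$data),
       positives = sum(labels))

  # --- rebalance + train + CV ---------------------------------------------
  cvrep <- repeated_stratified_cv(restricted, labels, cv = config$cv,
                                  clf_config = config$classifier,
                                  resample = config$resample)
  write_cv_report(cvrep, file.path(out_dir, "cv"))
  note("train", runs = cvrep$summary$n_runs,
       auc = round(cvrep$summary$auc[["mean"]], 4))

  # --- manifest ------------------------------------------------------------
  artifacts <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                            "manifest.json"))
  manifest <- list(
    config_fingerprint = config_fingerprint(config),
    master_seed = config$seed,
    artifacts = artifacts,
    artifact_hashes = stats::setNames(
      lapply(file.path(out_dir, artifacts), hash_file), artifacts),
    stages = stage_log,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  manifest$manifest_hash <- fnv1a(charToRaw(as.character(
    jsonlite::toJSON(manifest[c("config_fingerprint", "artifact_hashes")],
                     auto_unbox = TRUE))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(fm_masked = fm_masked, groups = strict, labels = labels,
                 imputations = sets, eval_report = ev, cv_report = cvrep,
                 manifest = manifest))
}

#' Load a pipeline configuration from a YAML/JSON file
#'
#' Schema (all keys optional): `seed`, `n_controls`, `n_patients`,
#' `frac_relaxed_only`, `alpha`, `variables` (per-variable overrides of
#' `missing_rate`), `imputation` (list of `{method, m, knn_k, rank,
#' max_iter, tol}`), `rebalance` (`smote_k`, `target_ratio`, `enn_k`),
#' `classifier` (`n_estimators`, `num_leaves`, `class_weight`), `cv`
#' (`n_splits`, `n_repeats`).  Unknown top-level keys are an error.
#'
#' @param path file path (`.yaml`/`.yml`/`.json`).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  known <- c("seed", "n_controls", "n_patients", "frac_relaxed_only",
             "alpha", "variables", "imputation", "rebalance", "classifier",
             "cv")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  vars <- default_variable_specs()
  for (nm in names(raw$variables %||% list())) {
    if (!nm %in% names(vars)) stop("unknown variable in config: ", nm)
    ov <- raw$variables[[nm]]
    if (!is.null(ov$missing_rate)) vars[[nm]]$missing_rate <- ov$missing_rate
  }
  gen <- cohort_gen_config(
    n_controls = raw$n_controls %||% 2130L,
    n_patients = raw$n_patients %||% 123L,
    variables = vars)
  imps <- if (is.null(raw$imputation)) NULL else lapply(raw$imputation,
    function(ic) do.call(imputation_config, ic))
  args <- list(gen = gen,
               frac_relaxed_only = raw$frac_relaxed_only %||% 0.08,
               alpha = raw$alpha %||% 0.05,
               seed = raw$seed %||% 1L)
  if (!is.null(imps)) args$imputation <- imps
  if (!is.null(raw$rebalance))
    args$resample <- do.call(resample_config, raw$rebalance)
  if (!is.null(raw$classifier))
    args$classifier <- do.call(classifier_config, raw$classifier)
  if (!is.null(raw$cv)) args$cv <- do.call(cv_config, raw$cv)
  do.call(pipeline_config, args)
}
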