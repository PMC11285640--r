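#' Assemble a full run configuration
#'
#' Bundles the stage configurations. Every stochastic stage derives its
#' seed deterministically from the master seed and a stage tag, so one
#' master seed fixes the entire run.
#'
#' @param seed Master seed.
#' @param simulation A [sim_config()] (its own seed field is overridden by
#'   the derived stage seed).
#' @param mlp An [mlp_control()].
#' @param gbc A [gbc_control()].
#' @param imputation An [imputation_config()].
#' @param split_fraction Training fraction.
#' @param threshold Classification threshold.
#' @param sensitivity Run the distort-impute-re-evaluate stage.
#' @param sensitivity_rate Masking rate for that stage.
#' @param boot_n Bootstrap resamples for AUC intervals.
#' @param paths Optional list with `claims_file` and `patients_file` to
#'   ingest real-format data instead of simulating.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, simulation = sim_config(),
                       mlp = mlp_control(), gbc = gbc_control(),
                       imputation = imputation_config(),
                       split_fraction = 0.8, threshold = 0.5,
                       sensitivity = TRUE, sensitivity_rate = 0.4,
                       boot_n = 2000, paths = NULL) {
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop_config("split_fraction", "must be in (0, 1)")
  }
  if (!is.null(paths) &&
      !all(c("claims_file", "patients_file") %in% names(paths))) {
    stop_config("paths", "needs claims_file and patients_file")
  }
  structure(list(seed = as.integer(seed), simulation = simulation,
                 mlp = mlp, gbc = gbc, imputation = imputation,
                 split_fraction = split_fraction, threshold = threshold,
                 sensitivity = sensitivity,
                 sensitivity_rate = sensitivity_rate,
                 boot_n = boot_n, paths = paths),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; nested maps
#' (`simulation`, `mlp`, `gbc`, `imputation`) mirror the corresponding
#' constructors. Unknown keys are an error before any computation.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "simulation", "mlp", "gbc", "imputation",
             "split_fraction", "threshold", "sensitivity",
             "sensitivity_rate", "boot_n", "paths")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop(sprintf("unknown configuration key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  build <- function(ctor, args) do.call(ctor, args %||% list())
  run_config(
    seed = raw$seed %||% 1L,
    simulation = build(sim_config, raw$simulation),
    mlp = build(mlp_control, raw$mlp),
    gbc = build(gbc_control, raw$gbc),
    imputation = build(imputation_config, raw$imputation),
    split_fraction = raw$split_fraction %||% 0.8,
    threshold = raw$threshold %||% 0.5,
    sensitivity = raw$sensitivity %||% TRUE,
    sensitivity_rate = raw$sensitivity_rate %||% 0.4,
    boot_n = raw$boot_n %||% 2000,
    paths = raw$paths
  )
}

#' Ingest external claims and patient files
#'
#' Reads the documented delimited-text schemas (the formats the simulator
#' writes), validates mandatory columns, and rejects malformed rows
#' (unparseable year, negative utilization days, unknown code system)
#' with per-reason counts.
#'
#' @param claims_file,patients_file Tab-delimited text files.
#' @return List with `patients`, `claims` and a `rejected` count vector.
#' @export
ingest_external <- function(claims_file, patients_file) {
  claims <- read.delim(claims_file, stringsAsFactors = FALSE,
                       colClasses = "character")
  patients <- read.delim(patients_file, stringsAsFactors = FALSE)
  need_c <- c("patient_id", "year", "code_system", "code", "utilization_days")
  need_p <- c("patient_id", "age_group", "gender", "race", "rural_urban", "hpsa")
  for (nm in need_c) {
    if (!nm %in% names(claims)) {
      stop(sprintf("claims file lacks mandatory column '%s'", nm), call. = FALSE)
    }
  }
  for (nm in need_p) {
    if (!nm %in% names(patients)) {
      stop(sprintf("patients file lacks mandatory column '%s'", nm), call. = FALSE)
    }
  }
  if (nrow(claims) == 0) stop("claims file is empty", call. = FALSE)
  year <- suppressWarnings(as.integer(claims$year))
  days <- suppressWarnings(as.numeric(claims$utilization_days))
  bad_year <- is.na(year)
  bad_days <- is.na(days) | days < 0
  bad_sys <- !claims$code_system %in% c("ICD9", "ICD10")
  keep <- !(bad_year | bad_days | bad_sys)
  rejected <- c(bad_year = sum(bad_year), bad_utilization = sum(bad_days),
                bad_code_system = sum(bad_sys))
  if (any(rejected > 0)) {
    warning(sprintf("rejected %d malformed claim row(s)", sum(!keep)))
  }
  claims <- claims[keep, need_c]
  claims$year <- year[keep]
  claims$utilization_days <- days[keep]
  list(patients = patients[, need_p], claims = claims, rejected = rejected)
}

#' Run the full pipeline
#'
#' Stage order: simulate (or ingest) claims, build the analysis cohort,
#' stratified split, exposure models and stabilized weights on the
#' training patients, weighted MSM + MLP + stacked ensemble, evaluation of
#' all three models on the held-out test set, feature rankings,
#' descriptive statistics, and optionally the sensitivity protocol. A
#' manifest records the derived seeds, a config hash, and record counts.
#'
#' @param config A [run_config()].
#' @param dir Optional directory to write artifacts (tables, reports,
#'   ROC points, manifest) as delimited text / JSON.
#' @return Object of class `ipm_run`.
#' @export
run_pipeline <- function(config, dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  master <- config$seed
  seeds <- list(
    simulate = derive_seed(master, "simulate"),
    controls = derive_seed(master, "controls"),
    split = derive_seed(master, "split"),
    eval = derive_seed(master, "evaluate"),
    impute = derive_seed(master, "impute")
  )

  if (is.null(config$paths)) {
    sim <- config$simulation
    sim$seed <- seeds$simulate
    raw <- simulate_cohort(sim)
    window <- c(sim$start_year, sim$end_year)
  } else {
    raw <- ingest_external(config$paths$claims_file, config$paths$patients_file)
    window <- range(raw$claims$year)
  }

  cohort <- build_cohort(raw$patients, raw$claims,
                         equal_controls = TRUE, seed = seeds$controls)
  enc <- encode_cohort(cohort)
  x <- enc[, predictor_names(), drop = FALSE]
  y <- enc$outcome
  split <- split_cohort(y, config$split_fraction, seeds$split)

  train_ids <- cohort$patient_id[split$train]
  panel_tr <- build_panel(raw$patients, raw$claims, window[1], window[2],
                          ids = train_ids)
  exposure <- fit_exposure_models(panel_tr)
  w <- compute_iptw(panel_tr, exposure)
  w_train <- w$weight[match(train_ids, w$patient_id)]

  fit <- ipm(x[split$train, , drop = FALSE], y[split$train],
             weights = w_train, mlp = config$mlp, gbc = config$gbc,
             threshold = config$threshold)

  pr <- predict(fit, x[split$test, , drop = FALSE])
  y_te <- y[split$test]
  reports <- list(
    MSM = evaluate_classifier(y_te, pr$pMSM, config$threshold,
                              boot_n = config$boot_n, seed = seeds$eval),
    MLP = evaluate_classifier(y_te, pr$pANN, config$threshold,
                              boot_n = config$boot_n, seed = seeds$eval),
    IPM = evaluate_classifier(y_te, pr$prob, config$threshold,
                              boot_n = config$boot_n, seed = seeds$eval)
  )
  comparison <- compare_models(reports)
  rankings <- list(msm = rank_msm_features(fit$msm),
                   mlp = rank_mlp_features(fit$mlp))
  descriptives <- descriptive_table(cohort)

  sens <- NULL
  if (isTRUE(config$sensitivity)) {
    imp <- config$imputation
    imp$seed <- seeds$impute
    w_full <- rep(1, nrow(x))
    w_full[split$train] <- w_train
    sens <- run_sensitivity(x, y, split, weights = w_full,
                            rate = config$sensitivity_rate,
                            imputation = imp, mlp = config$mlp,
                            gbc = config$gbc)
  }

  manifest <- list(
    master_seed = master, stage_seeds = seeds,
    config_hash = text_hash(config),
    package_version = as.character(packageVersion("adprogress")),
    n_patients = nrow(cohort), n_claims = nrow(raw$claims),
    n_train = length(split$train), n_test = length(split$test),
    cohort_hash = text_hash(enc),
    weights_hash = text_hash(round(w$weight, 12))
  )

  run <- structure(list(cohort = cohort, encoded = enc, split = split,
                        exposure = exposure, weights = w, fit = fit,
                        test_predictions = pr, reports = reports,
                        comparison = comparison, rankings = rankings,
                        descriptives = descriptives, sensitivity = sens,
                        manifest = manifest, config = config),
                   class = "ipm_run")
  if (!is.null(dir)) write_run(run, dir)
  run
}

#' @export
print.ipm_run <- function(x, ...) {
  cat(sprintf("Pipeline run: %d patients (%d train / %d test), master seed %d\n\n",
              x$manifest$n_patients, x$manifest$n_train, x$manifest$n_test,
              x$manifest$master_seed))
  print(x$comparison)
  if (!is.null(x$sensitivity)) {
    cat("\n"); print(x$sensitivity)
  }
  invisible(x)
}

# write run artifacts as delimited text and JSON
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(run$cohort, file.path(dir, "cohort.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(as.data.frame(run$weights), file.path(dir, "weights.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  for (nm in names(run$reports)) {
    write.table(run$reports[[nm]]$auc$roc,
                file.path(dir, sprintf("roc_%s.tsv", tolower(nm))),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  aucs <- run$comparison$auc
  report <- list(
    auc = setNames(as.list(aucs$auc), aucs$model),
    accuracy = setNames(
      lapply(run$reports, function(r) unname(r$metrics$overall["accuracy"])),
      names(run$reports)),
    mean_weight = attr(run$weights, "mean_weight"),
    sensitivity = if (!is.null(run$sensitivity)) {
      list(ipm_auc = run$sensitivity$ipm$auc,
           mlp_only_auc = run$sensitivity$mlp_only$auc)
    }
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
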