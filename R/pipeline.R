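# End-to-end orchestration: simulate or load a cohort, validate, impute,
# engineer features, fit both model modes, bootstrap the final models,
# cross-validate, compare, and write a reproducible report bundle with a
# run manifest. All randomness derives from one master seed.

#' Configuration for an end-to-end run
#'
#' @param preset Simulation preset name (see [cohort_preset()]), or `NULL`
#'   when file inputs are given.
#' @param panel_path,covariate_path,outcome_path Paths to delimited input
#'   tables (long-format panel; covariate and outcome tables keyed by
#'   subject). Ignored when `preset` is set.
#' @param n_subjects Cohort size for simulated runs.
#' @param modes Model modes to fit.
#' @param grid A `grid_spec`.
#' @param threshold Pruning significance level.
#' @param B Bootstrap replicates (0 disables the bootstrap stage).
#' @param K Cross-validation folds.
#' @param cutoff Suboptimal HRQoL cutoff.
#' @param seed Master seed (mandatory).
#' @param output_dir Directory for the report bundle.
#' @param bootstrap_refit `"full"` or `"frozen"` (see [bootstrap_bien()]).
#' @return A validated `run_config`.
#' @export
run_config <- function(preset = NULL, panel_path = NULL,
                       covariate_path = NULL, outcome_path = NULL,
                       n_subjects = 600L,
                       modes = c("non_symptom", "symptom_enhanced"),
                       grid = grid_spec(), threshold = 0.05,
                       B = 200L, K = 10L, cutoff = 40, seed,
                       output_dir = NULL,
                       bootstrap_refit = c("full", "frozen")) {
  if (missing(seed) || !is.numeric(seed))
    stop("`seed` is mandatory and must be an integer")
  bootstrap_refit <- match.arg(bootstrap_refit)
  modes <- match.arg(modes, c("non_symptom", "symptom_enhanced"),
                     several.ok = TRUE)
  if (is.null(preset)) {
    paths <- c(panel_path, covariate_path, outcome_path)
    if (length(paths) != 3L)
      stop("either `preset` or all three input paths must be given")
    absent <- paths[!file.exists(paths)]
    if (length(absent))
      stop("input file(s) not found: ", paste(absent, collapse = ", "))
  } else {
    preset <- match.arg(preset,
                        c("null", "pattern_driven", "covariate_driven"))
  }
  if (B < 0 || K < 2) stop("need B >= 0 and K >= 2")
  structure(list(preset = preset, panel_path = panel_path,
                 covariate_path = covariate_path,
                 outcome_path = outcome_path, n_subjects = n_subjects,
                 modes = modes, grid = grid, threshold = threshold,
                 B = as.integer(B), K = as.integer(K), cutoff = cutoff,
                 seed = as.integer(seed), output_dir = output_dir,
                 bootstrap_refit = bootstrap_refit),
            class = "run_config")
}

#' Load a run configuration from a YAML or JSON file
#'
#' Scalar fields of [run_config()] may be set in the file; `seed` is
#' mandatory. Grid settings go under a `grid:` block.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  }
  grid_args <- cfg$grid %||% list()
  cfg$grid <- NULL
  args <- cfg
  args$grid <- do.call(grid_spec, grid_args)
  do.call(run_config, args)
}

#' Validate cohort input tables
#'
#' Checks the panel against the canonical 37-item schema (item names, wave
#' labels, response domain, three waves per subject-item), subject
#' alignment across the three tables, covariate completeness, and outcome
#' values. Missingness above 2% of responses is reported as a warning
#' (runs proceed); schema violations are fatal errors.
#'
#' @param panel Long-format panel data frame, or a path to one.
#' @param covariates Covariate data frame or path.
#' @param outcome Outcome data frame (`subject`, `hrqol`) or path.
#' @return List with `errors` and `warnings` (character vectors) and
#'   `ok = length(errors) == 0`.
#' @export
validate_inputs <- function(panel, covariates, outcome) {
  read_tsv <- function(x) if (is.character(x))
    utils::read.delim(x, stringsAsFactors = FALSE) else x
  panel <- read_tsv(panel); covariates <- read_tsv(covariates)
  outcome <- read_tsv(outcome)
  errors <- character(); warnings_ <- character()
  items <- symptom_items()$item

  need <- c("subject", "item", "wave", "response")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    errors <- c(errors, paste("panel lacks column(s):",
                              paste(miss, collapse = ", ")))
    return(list(errors = errors, warnings = warnings_, ok = FALSE))
  }
  bad_item <- which(!(panel$item %in% items))
  if (length(bad_item))
    errors <- c(errors, sprintf(
      "unknown item '%s' (first at row %d; %d rows affected)",
      panel$item[bad_item[1L]], bad_item[1L], length(bad_item)))
  bad_wave <- which(!(panel$wave %in% .WAVES))
  if (length(bad_wave))
    errors <- c(errors, sprintf(
      "unknown wave '%s' (first at row %d)",
      panel$wave[bad_wave[1L]], bad_wave[1L]))
  bad_resp <- which(!(is.na(panel$response) | panel$response %in% 0:1))
  if (length(bad_resp))
    errors <- c(errors, sprintf(
      "response outside {0, 1, missing} (first at row %d)", bad_resp[1L]))
  if (!length(errors)) {
    tab <- table(panel$subject, panel$item)
    if (any(tab != 3L))
      errors <- c(errors,
                  "each (subject, item) needs exactly one record per wave")
    miss_rate <- mean(is.na(panel$response))
    if (miss_rate > 0.02)
      warnings_ <- c(warnings_, sprintf(
        "missingness %.1f%% exceeds the expected <2%%", 100 * miss_rate))
    subs <- unique(as.character(panel$subject))
    if (!"subject" %in% names(covariates)) {
      errors <- c(errors, "covariate table lacks a `subject` column")
    } else {
      cmiss <- setdiff(covariate_schema()$name, names(covariates))
      if (length(cmiss))
        errors <- c(errors, paste("covariate table lacks column(s):",
                                  paste(cmiss, collapse = ", ")))
      al <- setdiff(subs, as.character(covariates$subject))
      if (length(al))
        errors <- c(errors, paste("subject(s) missing from covariates:",
                                  paste(utils::head(al, 5L), collapse = ", ")))
    }
    if (!all(c("subject", "hrqol") %in% names(outcome))) {
      errors <- c(errors, "outcome table needs columns `subject`, `hrqol`")
    } else {
      al <- setdiff(subs, as.character(outcome$subject))
      if (length(al))
        errors <- c(errors, paste("subject(s) missing from outcome:",
                                  paste(utils::head(al, 5L), collapse = ", ")))
      if (!all(is.finite(outcome$hrqol)))
        errors <- c(errors, "non-finite HRQoL scores in outcome table")
    }
  }
  list(errors = errors, warnings = warnings_, ok = length(errors) == 0L)
}

#' Run the full analysis pipeline
#'
#' Stages: acquire cohort (simulate from a preset or load the three input
#' tables) -> validate -> impute -> cross-sectional measures -> pattern
#' features -> fit each mode with [bien_fit()] -> bootstrap each final
#' model -> cross-validate each mode with shared folds -> compare modes.
#' When `config$output_dir` is set, writes the pattern matrix, model
#' reports, bootstrap and CV reports, the comparison summary and a run
#' manifest; rerunning with an identical config reproduces identical
#' numbers.
#'
#' @param config A `run_config`.
#' @return List with `fits`, `bootstrap`, `cv`, `comparison`, `reports`,
#'   `manifest`, and the engineered `patterns`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- spawn_seeds(config$seed, c("cohort", "bootstrap", "cv"))

  if (!is.null(config$preset)) {
    cohort <- cohort_preset(config$preset, config$n_subjects,
                            seed = seeds[["cohort"]])
    panel <- cohort$panel; covariates <- cohort$covariates
    y <- cohort$outcome
  } else {
    panel_df <- utils::read.delim(config$panel_path,
                                  stringsAsFactors = FALSE)
    covariates <- utils::read.delim(config$covariate_path,
                                    stringsAsFactors = FALSE)
    outcome_df <- utils::read.delim(config$outcome_path,
                                    stringsAsFactors = FALSE)
    val <- validate_inputs(panel_df, covariates, outcome_df)
    for (w in val$warnings) warning(w, call. = FALSE)
    if (!val$ok)
      stop("input validation failed:\n  ",
           paste(val$errors, collapse = "\n  "))
    panel <- as_symptom_panel(panel_df)
    y <- stats::setNames(outcome_df$hrqol, outcome_df$subject)
    y <- y[panel$subjects]
  }

  panel <- impute_missing(panel)
  measures <- build_cross_sectional_measures(panel)
  patterns <- derive_pattern_features(measures)

  fits <- list(); boots <- list(); cvs <- list(); reports <- list()
  designs <- list()
  for (mode in config$modes) {
    X <- assemble_design_matrix(patterns, covariates, mode)
    designs[[mode]] <- X
    fits[[mode]] <- bien_fit(X, y, config$grid, config$threshold)
    if (config$B > 0) {
      boots[[mode]] <- bootstrap_bien(
        X, y, B = config$B, seed = seeds[["bootstrap"]],
        grid = config$grid, threshold = config$threshold,
        fit = fits[[mode]], refit = config$bootstrap_refit)
    }
    cvs[[mode]] <- cross_validated_auc(
      X, y, K = config$K, cutoff = config$cutoff, seed = seeds[["cv"]],
      grid = config$grid, threshold = config$threshold, mode = mode)
    reports[[mode]] <- model_report(fits[[mode]],
                                    attr(X, "column_info"),
                                    boots[[mode]])
  }
  comparison <- if (all(c("non_symptom", "symptom_enhanced") %in%
                          config$modes)) {
    compare_models(cvs[["non_symptom"]], cvs[["symptom_enhanced"]])
  } else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("symtraj")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, child_seeds = as.list(seeds),
    preset = config$preset, n_subjects = length(y),
    modes = config$modes, B = config$B, K = config$K,
    cutoff = config$cutoff, threshold = config$threshold,
    grid = unclass(config$grid),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  if (!is.null(config$output_dir)) {
    d <- config$output_dir
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_pattern_matrix(patterns, file.path(d, "pattern_matrix.tsv"))
    for (mode in config$modes) {
      utils::write.table(reports[[mode]],
                         file.path(d, paste0("model_", mode, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (config$B > 0)
        write_bootstrap_report(boots[[mode]],
                               file.path(d, paste0("bootstrap_", mode)),
                               attr(designs[[mode]], "column_info"))
      write_cv_report(cvs[[mode]], file.path(d, paste0("cv_", mode)))
    }
    if (!is.null(comparison))
      jsonlite::write_json(comparison, file.path(d, "comparison.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
    jsonlite::write_json(manifest, file.path(d, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(fits = fits, bootstrap = boots, cv = cvs, comparison = comparison,
       reports = reports, patterns = patterns, manifest = manifest)
}
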