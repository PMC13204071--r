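# Synthetic cohort generator. Each symptom item follows an independent
# two-state first-order Markov chain across the three survey waves:
#   P(present at T1) = pi,  P(present at t+1 | present at t) = rho,
#   P(present at t+1 | absent at t) = omega.
# Non-symptom covariates are drawn independently of symptoms; diagnoses are
# mutually exclusive (multinomial, one-hot coded). Outcomes are
# 50 + X beta + Gaussian noise, where X holds a known sparse set of
# trajectory-pattern (and optionally covariate) predictors.

# default transition parameters by domain: more prevalent domains (sensory,
# pain, anxiety) get higher initial prevalence; persistence and onset are
# chosen so consistent absence dominates and persistent presence stays rare
# (item-level P5 prevalence <= ~7%).
.DEFAULT_PI <- c(
  depression = 0.17, anxiety = 0.22, sensory = 0.22, motor = 0.10,
  cardiac = 0.10, respiratory = 0.10, memory = 0.17, pain = 0.22,
  gastrointestinal = 0.10, fatigue = 0.10
)
.DEFAULT_RHO <- 0.55
.DEFAULT_OMEGA <- 0.05

#' Per-item Markov transition parameters
#'
#' Defaults give each item an initial prevalence depending on its domain
#' (0.22 for sensory/pain/anxiety, 0.17 for depression/memory, 0.10
#' elsewhere), persistence `rho = 0.55` and onset `omega = 0.05`. Under
#' these dynamics consistent absence (P8) is by far the most frequent item
#' trajectory and persistent presence (P5) is rare, mirroring the
#' qualitative prevalence ordering seen in survivor cohorts.
#'
#' @param pi,rho,omega Optional scalar or 37-vector overrides (recycled).
#' @return Data frame with columns `item`, `pi`, `rho`, `omega`.
#' @export
default_item_params <- function(pi = NULL, rho = NULL, omega = NULL) {
  si <- symptom_items()
  out <- data.frame(
    item = si$item,
    pi = unname(.DEFAULT_PI[si$domain]),
    rho = .DEFAULT_RHO,
    omega = .DEFAULT_OMEGA,
    stringsAsFactors = FALSE
  )
  if (!is.null(pi)) out$pi <- rep_len(pi, 37L)
  if (!is.null(rho)) out$rho <- rep_len(rho, 37L)
  if (!is.null(omega)) out$omega <- rep_len(omega, 37L)
  out
}

#' Simulation configuration
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param item_params Data frame as from [default_item_params()]: one row
#'   per canonical item with initial prevalence `pi`, persistence `rho`
#'   (P(present | previously present)) and onset `omega`
#'   (P(present | previously absent)), all probabilities.
#' @param missing_rate Probability that any single (subject, item, wave)
#'   response is masked as missing, completely at random. Default 0.
#' @param seed Integer seed; fixed seed gives bit-identical cohorts.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_subjects, item_params = default_item_params(),
                              missing_rate = 0, seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1)
    stop("`n_subjects` must be a positive integer")
  items <- symptom_items()$item
  if (!setequal(item_params$item, items))
    stop("item_params must cover exactly the 37 canonical items")
  item_params <- item_params[match(items, item_params$item), , drop = FALSE]
  for (p in c("pi", "rho", "omega")) {
    bad <- which(item_params[[p]] < 0 | item_params[[p]] > 1 |
                   !is.finite(item_params[[p]]))
    if (length(bad))
      stop(sprintf("invalid probability `%s` for item(s): %s", p,
                   paste(item_params$item[bad], collapse = ", ")))
  }
  if (missing_rate < 0 || missing_rate >= 1)
    stop("`missing_rate` must be in [0, 1)")
  structure(list(n_subjects = as.integer(n_subjects),
                 item_params = item_params,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a three-wave symptom panel
#'
#' Item trajectories are independent two-state Markov chains with the
#' per-item parameters of `config`; optional missingness is applied
#' completely at random at `config$missing_rate`.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return A `symptom_panel`.
#' @export
#' @examples
#' cfg <- simulation_config(n_subjects = 50, seed = 7)
#' simulate_panel(cfg)
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  p <- config$item_params
  items <- p$item
  arr <- array(NA_integer_, dim = c(n, 37L, 3L),
               dimnames = list(paste0("S", seq_len(n)), items, .WAVES))
  pi_m <- matrix(p$pi, nrow = n, ncol = 37L, byrow = TRUE)
  rho_m <- matrix(p$rho, nrow = n, ncol = 37L, byrow = TRUE)
  omega_m <- matrix(p$omega, nrow = n, ncol = 37L, byrow = TRUE)
  arr[, , 1L] <- (matrix(stats::runif(n * 37L), n) < pi_m) * 1L
  for (w in 2:3) {
    prev <- arr[, , w - 1L]
    pr <- ifelse(prev == 1L, rho_m, omega_m)
    arr[, , w] <- (matrix(stats::runif(n * 37L), n) < pr) * 1L
  }
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * 37L * 3L), n) < config$missing_rate
    arr[mask] <- NA_integer_
  }
  symptom_panel(arr)
}

#' Simulate the non-symptom covariate table
#'
#' Ages and survey intervals are drawn from distributions matched to the
#' location and spread reported for long-term survivor cohorts (diagnosis
#' in childhood, first symptom survey in the mid-20s, third in the late
#' 30s, HRQoL survey a few years later). Diagnoses are mutually exclusive
#' (one-hot multinomial); treatment indicators are independent Bernoulli
#' draws with cohort-typical prevalences. Covariates are independent of
#' symptoms by construction.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @return Data frame with `subject` plus the 35 columns of
#'   [covariate_schema()].
#' @export
simulate_covariates <- function(n_subjects, seed = 1L) {
  set.seed(seed)
  n <- n_subjects
  age_dx <- pmin(pmax(stats::rnorm(n, 9.3, 5.5), 0), 21)
  age_t1 <- age_dx + pmax(stats::rnorm(n, 17.4, 4.0), 5)
  age_t3 <- age_t1 + pmax(stats::rnorm(n, 12.8, 2.5), 3)
  time_t3 <- pmax(stats::rnorm(n, 2.6, 1.5), 0.2)
  time_t1 <- (age_t3 - age_t1) + time_t3
  dx_prev <- c(dx_leukemia = 0.406, dx_hodgkin = 0.200,
               dx_non_hodgkin = 0.095, dx_osteosarcoma = 0.076,
               dx_wilms = 0.062, dx_cns = 0.050, dx_neuroblastoma = 0.042,
               dx_other = 0.068)
  dx_draw <- sample(names(dx_prev), n, replace = TRUE,
                    prob = dx_prev / sum(dx_prev))
  dx <- sapply(names(dx_prev), function(d) as.integer(dx_draw == d))
  tx_prev <- c(chemo_methotrexate = 0.533, chemo_it_methotrexate = 0.443,
               chemo_hd_methotrexate = 0.229, chemo_cytarabine = 0.307,
               chemo_it_cytarabine = 0.182, chemo_hd_cytarabine = 0.035,
               chemo_bleomycin = 0.061, chemo_alkylating = 0.648,
               chemo_anthracycline = 0.594, chemo_corticosteroid = 0.554,
               chemo_plant_alkaloid = 0.778, chemo_platinum = 0.064,
               rt_brain = 0.406, rt_neck = 0.325, rt_chest = 0.333,
               rt_abdomen = 0.280, rt_pelvis = 0.243,
               surgery_amputation = 0.054, surgery_other = 0.556)
  tx <- sapply(names(tx_prev),
               function(t) stats::rbinom(n, 1L, tx_prev[[t]]))
  out <- data.frame(
    subject = paste0("S", seq_len(n)),
    age_t1 = age_t1, time_t1_hrqol = time_t1, age_t3 = age_t3,
    time_t3_hrqol = time_t3, age_diagnosis = age_dx,
    sex_female = stats::rbinom(n, 1L, 0.517),
    race_white = stats::rbinom(n, 1L, 0.898),
    educ_college = stats::rbinom(n, 1L, 0.335),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(dx), as.data.frame(tx))
}

#' Specify the data-generating truth for simulated outcomes
#'
#' @param support Data frame with columns `measure`, `pattern` (P1-P10) and
#'   `beta` (HRQoL points per unit of the coded predictor); may have zero
#'   rows for a null outcome. Each (measure, pattern) pair must be a valid
#'   pattern-matrix column.
#' @param covariate_support Optional data frame with columns `name` (a
#'   covariate in [covariate_schema()]) and `beta`, for outcomes driven by
#'   non-symptom predictors.
#' @param intercept Baseline HRQoL (default 50, the population mean).
#' @param noise_sd Residual SD in HRQoL points (default 10, the population
#'   SD; 0 gives a deterministic outcome).
#' @return An object of class `true_model_spec`.
#' @export
true_model_spec <- function(support = NULL, covariate_support = NULL,
                            intercept = 50, noise_sd = 10) {
  if (is.null(support))
    support <- data.frame(measure = character(), pattern = character(),
                          beta = numeric(), stringsAsFactors = FALSE)
  valid_measures <- measure_schema()$measure
  bad <- !(support$measure %in% valid_measures) |
    !(support$pattern %in% .PATTERNS)
  if (any(bad))
    stop("invalid (measure, pattern) in support: ",
         paste(paste0(support$measure[bad], "/", support$pattern[bad]),
               collapse = ", "))
  if (!is.null(covariate_support)) {
    bad_cov <- !(covariate_support$name %in% covariate_schema()$name)
    if (any(bad_cov))
      stop("unknown covariate(s) in support: ",
           paste(covariate_support$name[bad_cov], collapse = ", "))
  }
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0")
  structure(list(support = support, covariate_support = covariate_support,
                 intercept = intercept, noise_sd = noise_sd),
            class = "true_model_spec")
}

#' Simulate HRQoL outcomes from a known sparse truth
#'
#' Computes the pattern feature matrix of the (complete) panel and returns
#' `y = intercept + X beta + eps`, `eps ~ N(0, noise_sd^2)`, where the
#' linear predictor runs over the trajectory-pattern support and, if given,
#' the covariate support of `truth`.
#'
#' @param panel A complete `symptom_panel` (impute first if needed).
#' @param covariates Covariate table (needed when `truth` has covariate
#'   support; otherwise optional).
#' @param truth A `true_model_spec`.
#' @param seed Integer seed for the noise draw.
#' @return Named numeric vector of HRQoL scores, one per subject.
#' @export
simulate_outcome <- function(panel, covariates = NULL, truth, seed = 1L) {
  stopifnot(inherits(truth, "true_model_spec"))
  if (anyNA(panel$responses))
    stop("panel has missing responses; impute before simulating outcomes")
  n <- length(panel$subjects)
  eta <- rep(truth$intercept, n)
  if (nrow(truth$support)) {
    pm <- derive_pattern_features(build_cross_sectional_measures(panel))
    cols <- paste0(truth$support$measure, "__", truth$support$pattern)
    eta <- eta + as.vector(pm[, cols, drop = FALSE] %*% truth$support$beta)
  }
  if (!is.null(truth$covariate_support) && nrow(truth$covariate_support)) {
    if (is.null(covariates))
      stop("truth has covariate support but no covariate table was given")
    cv <- covariates[match(panel$subjects, covariates$subject), , drop = FALSE]
    Xc <- as.matrix(cv[, truth$covariate_support$name, drop = FALSE])
    eta <- eta + as.vector(Xc %*% truth$covariate_support$beta)
  }
  set.seed(seed)
  y <- eta + stats::rnorm(n, 0, truth$noise_sd)
  names(y) <- panel$subjects
  y
}

#' Documented cohort presets
#'
#' Three named data-generating configurations used throughout the test
#' suite and examples:
#' \describe{
#'   \item{`null`}{No true effects: `y = 50 + N(0, 10^2)`, independent of
#'     every predictor.}
#'   \item{`pattern_driven`}{Five trajectory-pattern effects (absence
#'     patterns beneficial, persistence/escalation harmful, 3.5-5 HRQoL
#'     points in magnitude, residual SD 8); covariates carry no signal.}
#'   \item{`covariate_driven`}{Signal only in non-symptom covariates
#'     (female sex -3.2, college education +3.6, age at third survey -0.33
#'     per year, abdominal radiation -2.8; residual SD 8); symptom patterns
#'     carry no signal.}
#' }
#'
#' @param preset One of `"null"`, `"pattern_driven"`, `"covariate_driven"`.
#' @param n_subjects Cohort size (default 600).
#' @param seed Master seed; panel, covariates and noise use distinct
#'   deterministic child seeds.
#' @param missing_rate MCAR missingness applied to the panel (default 0).
#' @return List with `panel` (complete), `covariates`, `outcome`, `truth`,
#'   and `config`.
#' @export
#' @examples
#' ch <- cohort_preset("pattern_driven", n_subjects = 100, seed = 42)
#' summary(ch$outcome)
cohort_preset <- function(preset = c("null", "pattern_driven",
                                     "covariate_driven"),
                          n_subjects = 600, seed = 1L, missing_rate = 0) {
  preset <- match.arg(preset)
  truth <- switch(preset,
    null = true_model_spec(noise_sd = 10),
    pattern_driven = true_model_spec(
      support = data.frame(
        measure = c("feeling_weak", "chest_pain_with_exercise",
                    "weakness_leg", "depression_summary", "pain_summary"),
        pattern = c("P8", "P8", "P8", "P5", "P2"),
        beta = c(4.5, 5.0, 4.0, -5.0, -3.5),
        stringsAsFactors = FALSE
      ),
      noise_sd = 8
    ),
    covariate_driven = true_model_spec(
      covariate_support = data.frame(
        name = c("sex_female", "educ_college", "age_t3", "rt_abdomen"),
        beta = c(-3.2, 3.6, -0.33, -2.8),
        stringsAsFactors = FALSE
      ),
      noise_sd = 8
    )
  )
  seeds <- spawn_seeds(seed, c("panel", "covariates", "outcome"))
  config <- simulation_config(n_subjects, missing_rate = missing_rate,
                              seed = seeds[["panel"]])
  panel <- simulate_panel(config)
  complete <- if (missing_rate > 0) impute_missing(panel) else panel
  covariates <- simulate_covariates(n_subjects, seed = seeds[["covariates"]])
  outcome <- simulate_outcome(complete, covariates, truth,
                              seed = seeds[["outcome"]])
  list(panel = panel, covariates = covariates, outcome = outcome,
       truth = truth, config = config, preset = preset, seed = seed)
}

#' Write a simulated cohort as delimited tables plus a truth document
#'
#' The panel is written long-format (`subject`, `item`, `wave`,
#' `response`), covariates and outcome as tab-delimited tables keyed by
#' subject, and the data-generating truth as JSON.
#'
#' @param cohort A list as returned by [cohort_preset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("panel.tsv", "covariates.tsv", "outcome.tsv",
                            "truth.json"))
  utils::write.table(panel_to_long(cohort$panel), paths[1L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$covariates, paths[2L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(subject = names(cohort$outcome), hrqol = cohort$outcome),
    paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(support = cohort$truth$support,
         covariate_support = cohort$truth$covariate_support,
         intercept = cohort$truth$intercept,
         noise_sd = cohort$truth$noise_sd),
    paths[4L], dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
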