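# Out-of-sample discrimination for suboptimal HRQoL: 10-fold
# cross-validation rebuilding the entire selection procedure inside each
# training set, with AUC computed on pooled out-of-fold predictions
# against the dichotomized observed outcome (score < 40).

#' Dichotomize HRQoL scores at the suboptimal cutoff
#'
#' A score strictly below the cutoff (default 40, one SD below the
#' population mean of 50) is labelled suboptimal.
#'
#' @param scores Numeric HRQoL scores.
#' @param cutoff Cutoff in HRQoL points (default 40).
#' @return Logical vector (`TRUE` = suboptimal) with a `prevalence`
#'   attribute.
#' @export
#' @examples
#' dichotomize(c(39.99, 40, 50))
dichotomize <- function(scores, cutoff = 40) {
  if (!all(is.finite(scores))) stop("scores must be finite")
  lab <- scores < cutoff
  attr(lab, "prevalence") <- mean(lab)
  lab
}

#' Cross-validated AUC with full model rebuild per fold
#'
#' Subjects are partitioned at random (seeded) into `K` mutually exclusive
#' blocks whose sizes differ by at most one. For each fold the complete
#' selection procedure ([bien_fit()]) is rerun on the other `K - 1` blocks
#' — no selection, standardization statistic or hyperparameter choice sees
#' the held-out block — and continuous HRQoL is predicted on the held-out
#' subjects. The risk score is the negative predicted HRQoL; the headline
#' AUC pools all out-of-fold predictions against the dichotomized observed
#' outcome, with the per-fold min-max range reported alongside. Folds
#' containing a single observed class yield no fold AUC and are flagged.
#'
#' @param X Design matrix.
#' @param y Continuous HRQoL outcome.
#' @param K Number of folds (default 10).
#' @param cutoff Suboptimal cutoff (default 40).
#' @param seed Seed for the fold partition.
#' @param grid,threshold Passed to [bien_fit()].
#' @param mode Label stored in the report (`"symptom_enhanced"` or
#'   `"non_symptom"`), informational only.
#' @param stratified If `TRUE`, folds are stratified by the dichotomized
#'   outcome; default `FALSE` (simple random blocks).
#' @return A `cv_report`: `$auc_pooled`, `$auc_folds`, `$fold_range`,
#'   `$folds`, `$roc`, `$predictions`, `$flagged_folds`, `$cutoff`,
#'   `$seed`, `$mode`.
#' @export
cross_validated_auc <- function(X, y, K = 10L, cutoff = 40, seed = 1L,
                                grid = grid_spec(), threshold = 0.05,
                                mode = "symptom_enhanced",
                                stratified = FALSE) {
  xy <- .check_xy(X, y); X <- xy$X; y <- xy$y
  n <- length(y)
  labels <- dichotomize(y, cutoff)
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("need at least 2 subjects in each outcome class for AUC")
  set.seed(seed)
  if (stratified) {
    folds <- integer(n)
    for (cls in c(TRUE, FALSE)) {
      idx <- which(labels == cls)
      folds[idx] <- sample(rep_len(seq_len(K), length(idx)))
    }
  } else {
    folds <- sample(rep_len(seq_len(K), n))
  }
  pred <- rep(NA_real_, n)
  fold_models <- vector("list", K)
  for (k in seq_len(K)) {
    tr <- folds != k
    fit_k <- bien_fit(X[tr, , drop = FALSE], y[tr], grid, threshold)
    pred[!tr] <- predict(fit_k, X[!tr, , drop = FALSE])
    fold_models[[k]] <- fit_k
  }
  risk <- -pred
  auc_folds <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    te <- folds == k
    if (length(unique(labels[te])) == 2L)
      auc_folds[k] <- auc_rank(risk[te], labels[te])
  }
  flagged <- which(is.na(auc_folds))
  structure(
    list(auc_pooled = auc_rank(risk, labels),
         auc_folds = auc_folds,
         auc_fold_mean = mean(auc_folds, na.rm = TRUE),
         fold_range = range(auc_folds, na.rm = TRUE),
         folds = folds, roc = roc_points(risk, labels),
         predictions = data.frame(subject = rownames(X) %||%
                                    paste0("S", seq_len(n)),
                                  fold = folds, predicted = pred,
                                  observed = y,
                                  suboptimal = as.logical(labels)),
         fold_models = fold_models, flagged_folds = flagged,
         prevalence = attr(labels, "prevalence"),
         K = K, cutoff = cutoff, seed = seed, mode = mode,
         stratified = stratified),
    class = "cv_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
#' @method print cv_report
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "cv_report (%s): pooled AUC %.3f, fold range %.3f-%.3f (K = %d)\n",
    x$mode, x$auc_pooled, x$fold_range[1L], x$fold_range[2L], x$K))
  if (length(x$flagged_folds))
    cat("  single-class fold(s) without fold AUC:",
        paste(x$flagged_folds, collapse = ", "), "\n")
  invisible(x)
}

#' Compare cross-validated performance of two model modes
#'
#' Requires both reports to share the same fold assignment and observed
#' outcome (enforce by using the same seed and outcome), then summarises
#' per-fold paired AUC differences and the pooled difference.
#'
#' @param report_ns `cv_report` for the non-symptom mode.
#' @param report_se `cv_report` for the symptom-enhanced mode.
#' @return List with `pooled_diff` (symptom-enhanced minus non-symptom),
#'   `fold_diff`, `n_folds_improved`, `n_folds_compared`, and the two
#'   pooled AUCs.
#' @export
compare_models <- function(report_ns, report_se) {
  stopifnot(inherits(report_ns, "cv_report"), inherits(report_se, "cv_report"))
  if (!identical(report_ns$folds, report_se$folds))
    stop("fold assignments differ; rerun both modes with the same seed")
  if (!identical(report_ns$predictions$observed,
                 report_se$predictions$observed))
    stop("observed outcomes differ between reports")
  fd <- report_se$auc_folds - report_ns$auc_folds
  list(
    auc_non_symptom = report_ns$auc_pooled,
    auc_symptom_enhanced = report_se$auc_pooled,
    pooled_diff = report_se$auc_pooled - report_ns$auc_pooled,
    fold_diff = fd,
    n_folds_improved = sum(fd > 0, na.rm = TRUE),
    n_folds_compared = sum(!is.na(fd))
  )
}

#' Write a CV report as JSON plus a ROC point table
#'
#' @param report A `cv_report`.
#' @param path Base path; writes `<path>.json` and `<path>_roc.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_cv_report <- function(report, path) {
  js <- paste0(path, ".json"); roc <- paste0(path, "_roc.tsv")
  jsonlite::write_json(
    list(mode = report$mode, K = report$K, cutoff = report$cutoff,
         seed = report$seed, auc_pooled = report$auc_pooled,
         auc_fold_mean = report$auc_fold_mean,
         auc_folds = report$auc_folds, fold_range = report$fold_range,
         flagged_folds = report$flagged_folds,
         prevalence = report$prevalence),
    js, auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.table(report$roc, roc, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(js, roc))
}
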