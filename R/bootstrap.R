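# Post-selection inference by nonparametric bootstrap: resample subjects
# with replacement, rerun the complete selection procedure, record each
# original-model predictor's coefficient (zero when not selected), and
# summarise with empirical 95% CIs and selection probabilities.

#' Bootstrap a fitted selection model
#'
#' For each of `B` replicates, subjects are resampled with replacement and
#' the full fitting procedure (grid search and pruning; or, with
#' `refit = "frozen"`, candidate generation at the original winning
#' `(alpha, lambda)` followed by pruning) is rerun. Each predictor of the
#' original final model contributes its replicate coefficient, zero-filled
#' when unselected. Empirical CIs use symmetric order statistics
#' (`x_(k)`, `x_(B+1-k)`, `k = ceiling(0.025 B)`), under which a predictor
#' selected in at most 97.5% of replicates whose nonzero draws share one
#' sign necessarily has zero as one CI bound.
#'
#' @param X Design matrix.
#' @param y Outcome.
#' @param B Number of replicates (>= 1).
#' @param seed Master seed; per-replicate seeds are derived from it, so
#'   results do not depend on execution order.
#' @param grid,threshold Passed to [bien_fit()].
#' @param fit Optional precomputed original-data `bien_model`.
#' @param refit `"full"` (rerun the grid search, default) or `"frozen"`
#'   (reuse the original hyperparameters, faster).
#' @param level CI level (default 0.95).
#' @return A `bootstrap_report`: `$table` (predictor, estimate,
#'   selection_prob, ci_lower, ci_upper), `$coefficients` (B x p zero-filled
#'   draws), `$selection_freq` over all columns, `$B`, `$B_effective`,
#'   `$failures`, `$seed`.
#' @export
bootstrap_bien <- function(X, y, B = 1000L, seed = 1L, grid = grid_spec(),
                           threshold = 0.05, fit = NULL,
                           refit = c("full", "frozen"), level = 0.95) {
  refit <- match.arg(refit)
  xy <- .check_xy(X, y); X <- xy$X; y <- xy$y
  if (B < 1) stop("B must be >= 1")
  if (is.null(fit)) fit <- bien_fit(X, y, grid, threshold)
  preds <- fit$subset
  n <- length(y)
  draws <- matrix(0, nrow = B, ncol = length(preds),
                  dimnames = list(NULL, preds))
  sel_count <- stats::setNames(numeric(ncol(X)), colnames(X))
  rep_seeds <- spawn_seeds(seed, paste0("replicate_", seq_len(B)))
  ok <- rep(TRUE, B)
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch({
      if (refit == "full") {
        bien_fit(X[idx, , drop = FALSE], y[idx], grid, threshold)
      } else {
        Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
        keep <- apply(Xb, 2L, stats::var) > 0
        Xk <- Xb[, keep, drop = FALSE]
        sub <- if (is.finite(fit$lambda))
          generate_candidate_set(Xk, yb, fit$alpha, fit$lambda)
        else character()
        cand <- refit_mle(Xk, yb, sub)
        if (inherits(cand, "discarded_candidate"))
          cand <- refit_mle(Xk, yb, character())
        cand$alpha <- fit$alpha; cand$lambda <- fit$lambda
        prune(cand, Xk, yb, threshold)
      }
    }, error = function(e) e)
    if (inherits(fb, "error")) {
      ok[b] <- FALSE
      next
    }
    sel_count[fb$subset] <- sel_count[fb$subset] + 1
    hit <- intersect(preds, fb$subset)
    draws[b, hit] <- fb$coefficients[hit]
  }
  failures <- sum(!ok)
  draws <- draws[ok, , drop = FALSE]  # failed replicates carry no draws
  B_eff <- B - failures
  tab <- data.frame(
    predictor = preds,
    estimate = unname(fit$coefficients[preds]),
    selection_prob = if (length(preds))
      colSums(draws != 0) / max(B_eff, 1L) else numeric(0),
    stringsAsFactors = FALSE
  )
  if (length(preds)) {
    ci <- t(apply(draws, 2L, empirical_ci, level = level))
    tab$ci_lower <- ci[, "lower"]
    tab$ci_upper <- ci[, "upper"]
  } else {
    tab$ci_lower <- numeric(0); tab$ci_upper <- numeric(0)
  }
  structure(
    list(table = tab, coefficients = draws,
         selection_freq = sel_count / max(B_eff, 1L),
         B = B, B_effective = B_eff, failures = failures,
         seed = seed, level = level, refit = refit),
    class = "bootstrap_report")
}

#' @export
#' @method print bootstrap_report
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("bootstrap_report: B = %d (%d effective), %d predictor(s)\n",
              x$B, x$B_effective, nrow(x$table)))
  if (nrow(x$table)) {
    tab <- x$table
    tab$selection_pct <- sprintf("%.0f%%", 100 * tab$selection_prob)
    print(tab[, c("predictor", "estimate", "ci_lower", "ci_upper",
                  "selection_pct")], row.names = FALSE)
  }
  invisible(x)
}

#' Write a bootstrap report as JSON and a delimited table
#'
#' @param report A `bootstrap_report`.
#' @param path Base path; writes `<path>.json` and `<path>.tsv`.
#' @param column_info Optional design column metadata for pattern labels.
#' @return Invisibly, the paths written.
#' @export
write_bootstrap_report <- function(report, path, column_info = NULL) {
  tab <- report$table
  if (!is.null(column_info)) {
    idx <- match(tab$predictor, column_info$column)
    lab <- pattern_labels()
    tab$pattern_type <- ifelse(
      is.na(column_info$pattern[idx]), NA_character_,
      paste0(column_info$pattern[idx], ". ", lab[column_info$pattern[idx]]))
  }
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(B = report$B, B_effective = report$B_effective,
         failures = report$failures, seed = report$seed,
         level = report$level, table = tab,
         selection_freq = as.list(report$selection_freq[
           report$selection_freq > 0])),
    js, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
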