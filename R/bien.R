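# BIC-guided elastic net selection/estimation ("BIEN") for a continuous
# outcome, in five components:
#   (1) elastic net generates candidate predictor subsets along a
#       regularization path;
#   (2) each subset is refit by Gaussian maximum likelihood (OLS);
#   (3) candidates are scored by BIC = -2 loglik + k log n, with k counting
#       intercept, slopes and the error variance;
#   (4) a truncated grid search over (alpha, lambda) walks each lambda path
#       from strong to weak penalty and abandons it after `patience`
#       consecutive non-improving steps;
#   (5) the winning subset is pruned by backward elimination on refit
#       p-values.
# Penalization standardizes columns internally; estimates are reported on
# the original predictor scale.

#' Hyperparameter grid for the selection engine
#'
#' @param alpha Elastic net mixing values in (0, 1] (1 = lasso); must be
#'   distinct.
#' @param nlambda Number of penalty strengths per mixing value, log-spaced
#'   from the smallest lambda that selects nothing down to
#'   `lambda_min_ratio` times it.
#' @param lambda_min_ratio Ratio of smallest to largest lambda (default
#'   1e-4).
#' @param patience Consecutive non-improving BIC evaluations tolerated
#'   before a lambda path is abandoned (>= 1; `Inf` disables truncation).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(alpha = c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0),
                      nlambda = 100L, lambda_min_ratio = 1e-4,
                      patience = 5) {
  if (any(alpha <= 0 | alpha > 1)) stop("alpha values must lie in (0, 1]")
  if (anyDuplicated(alpha)) stop("alpha values must be distinct")
  if (patience < 1) stop("patience must be >= 1")
  if (nlambda < 1 || lambda_min_ratio <= 0 || lambda_min_ratio >= 1)
    stop("invalid lambda path specification")
  structure(list(alpha = sort(alpha, decreasing = TRUE),
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 patience = patience),
            class = "grid_spec")
}

.check_xy <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(is.finite(X))) stop("non-finite values in X")
  if (!all(is.finite(y))) stop("non-finite values in y")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  list(X = X, y = y)
}

# lambda path per alpha, matching the standard strong-penalty start:
# lambda_max = max_j |<x_j~, y - ybar>| / (n * max(alpha, 1e-3)) with
# columns standardized using the 1/n variance convention.
.lambda_path <- function(X, y, alpha, grid) {
  n <- nrow(X)
  xm <- colMeans(X)
  xs <- sqrt(colMeans(X^2) - xm^2)
  xs[xs == 0] <- 1
  g <- abs(as.vector(crossprod(sweep(sweep(X, 2, xm), 2, xs, "/"),
                               y - mean(y))))
  lmax <- max(g) / (n * max(alpha, 1e-3))
  if (lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * grid$lambda_min_ratio),
          length.out = grid$nlambda))
}

#' Generate an elastic net candidate predictor subset
#'
#' Fits the elastic net at mixing `alpha` and penalty `lambda` (columns
#' standardized internally) and returns the predictors with nonzero
#' coefficients. `lambda = 0` is the unpenalized limit: all non-constant
#' columns are returned.
#'
#' @param X Numeric design matrix (zero-variance columns are ignored).
#' @param y Numeric outcome.
#' @param alpha Elastic net mixing in (0, 1].
#' @param lambda Penalty strength (>= 0).
#' @return Character vector of selected column names (possibly empty).
#' @export
generate_candidate_set <- function(X, y, alpha, lambda) {
  xy <- .check_xy(X, y); X <- xy$X; y <- xy$y
  if (lambda < 0) stop("lambda must be >= 0")
  keep <- which(apply(X, 2L, stats::var) > 0)
  if (length(keep) == 0L) return(character())
  if (lambda == 0) return(colnames(X)[keep])
  Xk <- X[, keep, drop = FALSE]
  if (ncol(Xk) == 1L) {
    # soft-threshold on the single standardized column
    n <- nrow(Xk)
    z <- (Xk - mean(Xk)) / sqrt(mean((Xk - mean(Xk))^2))
    g <- abs(sum(z * (y - mean(y)))) / n
    return(if (g > lambda * alpha) colnames(Xk) else character())
  }
  path <- sort(unique(c(.lambda_path(Xk, y, alpha,
                                     grid_spec(nlambda = 30L)), lambda)),
               decreasing = TRUE)
  fit <- glmnet::glmnet(Xk, y, alpha = alpha, lambda = path,
                        standardize = TRUE, thresh = 1e-9)
  cf <- withCallingHandlers(
    glmnet::coef.glmnet(fit, s = lambda, exact = TRUE, x = Xk, y = y,
                        alpha = alpha, standardize = TRUE, thresh = 1e-9),
    warning = function(w) {
      # near-duplicate lambdas in the solved path trigger a harmless
      # interpolation warning even under exact refitting
      if (grepl("collapsing to unique", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  nz <- rownames(cf)[which(as.vector(cf) != 0)]
  setdiff(nz, "(Intercept)")
}

#' Refit a candidate subset by Gaussian maximum likelihood
#'
#' Ordinary least squares of `y` on the subset plus intercept; the Gaussian
#' log-likelihood uses the MLE error variance `RSS/n`. Coefficients are on
#' the original predictor scale.
#'
#' @param X Design matrix.
#' @param y Outcome.
#' @param subset Character vector of column names (may be empty for the
#'   intercept-only model).
#' @return A `candidate_model` (subset, coefficients, rss, loglik, k, n,
#'   bic), or a `discarded_candidate` carrying the reason when the
#'   submatrix is rank deficient or the subset is too large to fit.
#' @export
refit_mle <- function(X, y, subset = character()) {
  xy <- .check_xy(X, y); X <- xy$X; y <- xy$y
  n <- length(y)
  if (anyDuplicated(subset)) stop("duplicate columns in subset")
  p <- length(subset)
  if (p >= n - 1L)
    return(structure(list(reason = "subset size must be below n - 1"),
                     class = "discarded_candidate"))
  Xm <- cbind(`(Intercept)` = 1, X[, subset, drop = FALSE])
  qr_ <- qr(Xm)
  if (qr_$rank < ncol(Xm))
    return(structure(list(reason = "rank-deficient submatrix"),
                     class = "discarded_candidate"))
  beta <- qr.coef(qr_, y)
  res <- y - as.vector(Xm %*% beta)
  rss <- sum(res^2)
  sigma2 <- rss / n
  loglik <- if (sigma2 > 0) -n / 2 * (log(2 * pi * sigma2) + 1) else Inf
  k <- p + 2L  # intercept + slopes + error variance
  model <- structure(
    list(subset = subset, coefficients = beta, rss = rss, loglik = loglik,
         k = k, n = n, qr = qr_, residuals = res),
    class = "candidate_model")
  model$bic <- score_bic(model)
  model
}

#' Bayesian Information Criterion of a candidate model
#'
#' `BIC = -2 loglik + k log(n)` with `k` counting the intercept, the slopes
#' and the error variance.
#'
#' @param model A `candidate_model`.
#' @return The BIC value (may be `-Inf` for an interpolating fit).
#' @export
score_bic <- function(model) {
  if (model$n <= 1L) stop("BIC requires n > 1")
  -2 * model$loglik + model$k * log(model$n)
}

# TRUE if candidate a beats b under: lower BIC, then smaller subset, then
# larger lambda, then lexicographically earlier subset.
.beats <- function(a, b, tol = 1e-9) {
  if (is.null(b)) return(TRUE)
  if (a$bic < b$bic - tol) return(TRUE)
  if (a$bic > b$bic + tol) return(FALSE)
  if (length(a$subset) != length(b$subset))
    return(length(a$subset) < length(b$subset))
  la <- if (is.null(a$lambda)) Inf else a$lambda
  lb <- if (is.null(b$lambda)) Inf else b$lambda
  if (la != lb) return(la > lb)
  paste(sort(a$subset), collapse = "|") < paste(sort(b$subset), collapse = "|")
}

#' Truncated grid search over penalty forms and strengths
#'
#' For every mixing value, walks the lambda path from the strongest penalty
#' downward, generating candidate subsets, refitting by maximum likelihood
#' and scoring by BIC. A path is abandoned once `patience` consecutive
#' evaluations fail to improve the best BIC seen on that path. The
#' intercept-only candidate is always evaluated. Ties break toward the
#' smaller subset, then the larger lambda, then lexicographic column order.
#'
#' @param X Design matrix (zero-variance columns are dropped internally).
#' @param y Outcome.
#' @param grid A `grid_spec`.
#' @return The minimum-BIC `candidate_model` over all visited grid points,
#'   with `alpha`/`lambda` provenance and a `search_log` attribute counting
#'   evaluated and discarded candidates.
#' @export
truncated_grid_search <- function(X, y, grid = grid_spec()) {
  xy <- .check_xy(X, y); X <- xy$X; y <- xy$y
  keep <- which(apply(X, 2L, stats::var) > 0)
  X <- X[, keep, drop = FALSE]
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L; n_discard <- 0L
  refit_cached <- function(subset) {
    key <- paste0("s:", paste(sort(subset), collapse = "|"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    m <- refit_mle(X, y, subset)
    n_eval <<- n_eval + 1L
    if (inherits(m, "discarded_candidate")) n_discard <<- n_discard + 1L
    cache[[key]] <- m
    m
  }

  best <- refit_cached(character())
  best$lambda <- Inf; best$alpha <- NA_real_

  if (ncol(X) > 0L) {
    # the path is solved lazily in chunks so that abandoning it early also
    # skips the expensive dense tail of the regularization path
    chunk <- max(15L, min(3L * max(1, min(grid$patience, 100L)), 50L))
    for (alpha in grid$alpha) {
      path <- .lambda_path(X, y, alpha, grid)
      get_subsets <- function(upto) {
        if (ncol(X) >= 2L) {
          fit <- glmnet::glmnet(X, y, alpha = alpha,
                                lambda = path[seq_len(upto)],
                                standardize = TRUE, thresh = 1e-9)
          B <- fit$beta
          lapply(seq_len(ncol(B)), function(j) rownames(B)[which(B[, j] != 0)])
        } else {
          lapply(path[seq_len(upto)],
                 function(l) generate_candidate_set(X, y, alpha, l))
        }
      }
      path_best <- Inf; bad <- 0; j <- 1L
      solved_upto <- 0L; subsets <- NULL; prev_key <- NULL
      while (j <= length(path)) {
        if (j > solved_upto) {
          solved_upto <- min(solved_upto + chunk, length(path))
          subsets <- get_subsets(solved_upto)
        }
        if (j > length(subsets)) break  # solver returned a shorter path
        key_j <- paste(sort(subsets[[j]]), collapse = "|")
        if (identical(key_j, prev_key)) {
          # same candidate set as the previous lambda: not a new step
          j <- j + 1L
          next
        }
        prev_key <- key_j
        cand <- refit_cached(subsets[[j]])
        if (inherits(cand, "discarded_candidate")) {
          bad <- bad + 1
        } else {
          cand$lambda <- path[j]; cand$alpha <- alpha
          if (cand$bic < path_best - 1e-9) {
            path_best <- cand$bic; bad <- 0
          } else bad <- bad + 1
          if (.beats(cand, best)) best <- cand
        }
        if (bad >= grid$patience) break
        j <- j + 1L
      }
    }
  }
  attr(best, "search_log") <- list(evaluated = n_eval, discarded = n_discard)
  best
}

#' Backward-elimination pruning of a selected model
#'
#' Iteratively refits the model by OLS and removes the predictor with the
#' largest two-sided p-value while it exceeds `threshold` (one removal per
#' iteration), stopping when every retained predictor is significant at
#' `threshold` or the model is intercept-only. The final refit defines the
#' reported estimates.
#'
#' @param model A `candidate_model` fit on the full data.
#' @param X,y The data the model was fit on.
#' @param threshold Significance level for retention (default 0.05).
#' @return A `bien_model`: retained subset, coefficients (original scale),
#'   intercept, BIC, per-predictor p-values, and search provenance.
#' @export
prune <- function(model, X, y, threshold = 0.05) {
  xy <- .check_xy(X, y); X <- xy$X; y <- xy$y
  subset <- model$subset
  repeat {
    fit <- refit_mle(X, y, subset)
    if (inherits(fit, "discarded_candidate"))
      stop("pruning refit failed: ", fit$reason)
    pv <- .refit_pvalues(fit)
    if (length(subset) == 0L || all(pv <= threshold)) break
    subset <- setdiff(subset, names(pv)[which.max(pv)])
  }
  structure(
    list(subset = subset,
         coefficients = fit$coefficients[subset],
         intercept = unname(fit$coefficients["(Intercept)"]),
         p_values = pv, bic = fit$bic, loglik = fit$loglik, k = fit$k,
         n = fit$n, rss = fit$rss,
         alpha = model$alpha, lambda = model$lambda,
         threshold = threshold),
    class = "bien_model")
}

# two-sided t-test p-values for the slope coefficients of a candidate_model
.refit_pvalues <- function(fit) {
  p <- length(fit$subset)
  if (p == 0L) return(stats::setNames(numeric(0), character(0)))
  n <- fit$n
  df <- n - p - 1L
  sigma2 <- fit$rss / df
  R <- qr.R(fit$qr)
  XtX_inv <- chol2inv(R)
  se <- sqrt(diag(XtX_inv) * sigma2)[-1L]
  tval <- fit$coefficients[fit$subset] / se
  pv <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  stats::setNames(pv, fit$subset)
}

#' Fit a sparse linear model by BIC-guided elastic net selection
#'
#' Runs the full five-component procedure: zero-variance and duplicate
#' columns are set aside, the truncated grid search picks the minimum-BIC
#' elastic net candidate (always including the intercept-only model), and
#' backward elimination prunes predictors whose refit p-values exceed
#' `threshold`. Deterministic given its inputs.
#'
#' @param X Numeric design matrix with column names.
#' @param y Numeric outcome.
#' @param grid A `grid_spec`.
#' @param threshold Pruning significance level (default 0.05).
#' @return A `bien_model`; `$removed_columns` records columns set aside
#'   before fitting.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200 * 5), 200, dimnames = list(NULL, paste0("x", 1:5)))
#' y <- 50 + 4 * X[, 2] + rnorm(200)
#' bien_fit(X, y)$subset
bien_fit <- function(X, y, grid = grid_spec(), threshold = 0.05) {
  xy <- .check_xy(X, y); X <- xy$X; y <- xy$y
  const <- apply(X, 2L, stats::var) == 0
  dup <- duplicated(t(X))
  removed <- data.frame(
    column = colnames(X)[const | dup],
    reason = ifelse(const[const | dup], "zero variance", "duplicate"),
    stringsAsFactors = FALSE
  )
  Xu <- X[, !(const | dup), drop = FALSE]
  best <- truncated_grid_search(Xu, y, grid)
  out <- prune(best, Xu, y, threshold)
  out$removed_columns <- removed
  out$search_log <- attr(best, "search_log")
  out
}

#' @export
#' @method print bien_model
print.bien_model <- function(x, ...) {
  cat(sprintf("bien_model: %d predictor(s), BIC %.2f (n = %d)\n",
              length(x$subset), x$bic, x$n))
  cat(sprintf("  intercept: %.3f\n", x$intercept))
  if (length(x$subset)) {
    tab <- data.frame(estimate = round(x$coefficients, 4),
                      p_value = signif(x$p_values, 3))
    print(tab)
  }
  invisible(x)
}

#' Predict HRQoL scores from a fitted model
#'
#' @param object A `bien_model`.
#' @param newX Design matrix containing at least the model's selected
#'   columns.
#' @param ... Unused.
#' @return Numeric vector of predicted scores.
#' @export
#' @method predict bien_model
predict.bien_model <- function(object, newX, ...) {
  if (!is.matrix(newX)) newX <- as.matrix(newX)
  missing_cols <- setdiff(object$subset, colnames(newX))
  if (length(missing_cols))
    stop("newX lacks model column(s): ", paste(missing_cols, collapse = ", "))
  object$intercept +
    as.vector(newX[, object$subset, drop = FALSE] %*% object$coefficients)
}

#' Tabulate a fitted model for reporting
#'
#' Produces the standard report layout: predictor name, pattern type (for
#' trajectory predictors), and estimate; bootstrap columns are merged in
#' when a bootstrap report is supplied.
#'
#' @param model A `bien_model`.
#' @param column_info Optional `column_info` attribute of the design matrix
#'   used for fitting, to label pattern types.
#' @param bootstrap Optional `bootstrap_report` for CI/selection columns.
#' @return Data frame, first row the intercept.
#' @export
model_report <- function(model, column_info = NULL, bootstrap = NULL) {
  pat <- rep(NA_character_, length(model$subset))
  if (!is.null(column_info)) {
    idx <- match(model$subset, column_info$column)
    lab <- pattern_labels()
    pat <- ifelse(is.na(column_info$pattern[idx]), NA_character_,
                  paste0(column_info$pattern[idx], ". ",
                         lab[column_info$pattern[idx]]))
  }
  out <- data.frame(
    predictor = c("(Intercept)", model$subset),
    pattern_type = c(NA_character_, pat),
    estimate = c(model$intercept, unname(model$coefficients)),
    stringsAsFactors = FALSE
  )
  if (!is.null(bootstrap)) {
    m <- match(out$predictor, bootstrap$table$predictor)
    out$ci_lower <- bootstrap$table$ci_lower[m]
    out$ci_upper <- bootstrap$table$ci_upper[m]
    out$selection_pct <- 100 * bootstrap$table$selection_prob[m]
  }
  out
}
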