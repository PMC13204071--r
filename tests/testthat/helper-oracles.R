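# Independent oracles and fixture builders. These deliberately avoid the
# package's own computational paths.

# OLS by explicit normal equations (independent of refit_mle's QR route)
ols_normal_equations <- function(X, y, subset) {
  Xm <- cbind(1, X[, subset, drop = FALSE])
  solve(crossprod(Xm), crossprod(Xm, y))[, 1L]
}

# AUC by exhaustive all-pairs comparison, ties counted one half
auc_all_pairs <- function(risk, case) {
  case <- as.logical(case)
  pos <- risk[case]; neg <- risk[!case]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# brute-force best-subset search by BIC over all 2^p subsets
best_subset_bic <- function(X, y) {
  p <- ncol(X)
  best <- Inf
  for (m in 0:(2^p - 1)) {
    subset <- colnames(X)[bitwAnd(m, 2^(seq_len(p) - 1L)) > 0]
    fit <- refit_mle(X, y, subset)
    if (!inherits(fit, "discarded_candidate") && fit$bic < best)
      best <- fit$bic
  }
  best
}

# an all-absent panel with selected item trajectories overridden;
# trajs: named list item -> c(t1, t2, t3), one subject
panel_with_trajectories <- function(trajs, n_extra = 0L) {
  items <- symptom_items()$item
  n <- 1L + n_extra
  arr <- array(0L, dim = c(n, 37L, 3L),
               dimnames = list(paste0("S", seq_len(n)), items,
                               c("T1", "T2", "T3")))
  for (it in names(trajs)) arr[1L, it, ] <- as.integer(trajs[[it]])
  symptom_panel(arr)
}

# long-format records for one subject-item across the three waves
long_records <- function(subject, item, resp) {
  data.frame(subject = subject, item = item, wave = c("T1", "T2", "T3"),
             response = resp, stringsAsFactors = FALSE)
}

# a complete well-formed long panel for n subjects (every item, all waves)
long_panel_complete <- function(n, seed = 1L) {
  panel_to_long(simulate_panel(simulation_config(n, seed = seed)))
}

# random regression fixture with named columns
random_design <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
}
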