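# small numeric helpers shared across modules

#' Derive deterministic child seeds from a master seed
#'
#' Every source of randomness in a run is seeded from one master seed via
#' named child seeds, so serial and staged execution give identical
#' results.
#'
#' @param master Integer master seed.
#' @param labels Character vector naming the stages.
#' @return Named integer vector of seeds in `[1, 2^31 - 2]`.
#' @export
spawn_seeds <- function(master, labels) {
  m <- 2147483647  # 2^31 - 1 (Mersenne prime; multiplicative congruential)
  x <- (as.numeric(master) %% (m - 1)) + 1
  out <- integer(length(labels))
  for (i in seq_along(labels)) {
    # per-label offset from a simple polynomial character hash
    h <- sum(utf8ToInt(labels[i]) * seq_along(utf8ToInt(labels[i])))
    x <- (x * 48271 + h) %% m
    if (x == 0) x <- 1
    out[i] <- as.integer(x)
  }
  names(out) <- labels
  out
}

#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' AUC is the probability that a randomly chosen case carries a higher risk
#' score than a randomly chosen non-case, with ties counted one half;
#' computed from midranks, equivalent to the normalized Mann-Whitney U
#' statistic.
#'
#' @param risk Numeric risk scores (higher = more likely case).
#' @param case Logical/0-1 vector of case status.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(risk, case) {
  case <- as.logical(case)
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both outcome classes must be present")
  r <- rank(risk)
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param risk Numeric risk scores.
#' @param case Logical/0-1 case status.
#' @return Data frame of `(fpr, tpr)` pairs from (0,0) to (1,1), one step
#'   per distinct risk threshold.
#' @export
roc_points <- function(risk, case) {
  case <- as.logical(case)
  ord <- order(risk, decreasing = TRUE)
  risk <- risk[ord]; case <- case[ord]
  keep <- !duplicated(risk, fromLast = TRUE)  # last index of each tie group
  tpr <- cumsum(case)[keep] / sum(case)
  fpr <- cumsum(!case)[keep] / sum(!case)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

# symmetric order-statistic bootstrap CI: lower = x_(k), upper = x_(B+1-k),
# k = ceiling(alpha/2 * B). This makes the zero-bound property of
# zero-filled distributions exact (see the methods vignette).
empirical_ci <- function(draws, level = 0.95) {
  b <- length(draws)
  k <- max(1L, ceiling((1 - level) / 2 * b))
  s <- sort(draws)
  c(lower = s[k], upper = s[b + 1L - k])
}
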