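# Feature engineering: 48 cross-sectional measures per wave (37 item
# indicators + 11 count summaries) and 480 longitudinal change-pattern
# predictors (48 measures x patterns P1-P10).
#
# Coding conventions:
#   * item-level P1-P10 are 0/1 trajectory indicators;
#   * summary-level escalation/resolution (P1-P4) are continuous counts of
#     member items exhibiting the item-level pattern, ranging 0..n_members;
#   * summary-level persistence/absence (P5-P10) apply the trajectory rule
#     to the any-symptom indicator (count > 0) at each wave.

#' Build the 48 cross-sectional symptom measures per wave
#'
#' For every subject and wave, computes the 37 item indicators and the 11
#' aggregated counts: eight multi-item individual domains (memory and
#' gastrointestinal are single-item and not summarised), the psychological
#' (12 items) and physical (25 items) global domains, and the overall count
#' of all 37 items.
#'
#' @param panel A complete (post-imputation) `symptom_panel`.
#' @return An object of class `measure_set`: numeric array
#'   `n_subjects x 48 x 3` with a `measure_info` attribute (columns
#'   `measure`, `kind`, `n_members`).
#' @export
build_cross_sectional_measures <- function(panel) {
  stopifnot(inherits(panel, "symptom_panel"))
  r <- panel$responses
  if (anyNA(r))
    stop("panel contains missing responses; run impute_missing() first")
  schema <- measure_schema()
  items <- symptom_items()$item
  n <- dim(r)[1L]
  out <- array(0, dim = c(n, nrow(schema), 3L),
               dimnames = list(panel$subjects, schema$measure, .WAVES))
  for (w in seq_along(.WAVES)) {
    rw <- r[, , w, drop = FALSE][, , 1L]
    if (n == 1L) rw <- matrix(rw, nrow = 1L, dimnames = list(NULL, items))
    out[, items, w] <- rw
    for (j in which(schema$kind == "summary")) {
      out[, j, w] <- rowSums(rw[, schema$members[[j]], drop = FALSE])
    }
  }
  structure(out, measure_info = schema[, c("measure", "kind", "n_members")],
            class = c("measure_set", "array"))
}

# item-level trajectory pattern indicators from a 0/1 array [n x m x 3]
.trajectory_patterns <- function(a) {
  slice <- function(w) {
    m <- a[, , w, drop = FALSE]
    dim(m) <- dim(a)[1:2]
    dimnames(m) <- dimnames(a)[1:2]
    m
  }
  t1 <- slice(1L); t2 <- slice(2L); t3 <- slice(3L)
  list(
    P1 = (1 - t1) * t2,             # absent T1, present T2
    P2 = (1 - t2) * t3,             # absent T2, present T3
    P3 = t1 * (1 - t2),             # present T1, absent T2
    P4 = t2 * (1 - t3),             # present T2, absent T3
    P5 = t1 * t2 * t3,              # + + +
    P6 = t1 * t2 * (1 - t3),        # + + -
    P7 = (1 - t1) * t2 * t3,        # - + +
    P8 = (1 - t1) * (1 - t2) * (1 - t3),  # - - -
    P9 = (1 - t1) * (1 - t2) * t3,  # - - +
    P10 = t1 * (1 - t2) * (1 - t3)  # + - -
  )
}

#' Derive the 480 longitudinal symptom change pattern predictors
#'
#' Applies the ten trajectory patterns to each of the 48 cross-sectional
#' measures. Item measures yield 0/1 indicators for every pattern. For the
#' 11 summaries, escalation/resolution patterns (P1-P4) are coded as the
#' number of member items exhibiting the item-level pattern (a continuous
#' burden-of-change measure in `0..n_members`), while persistence/absence
#' patterns (P5-P10) are 0/1 indicators obtained by applying the trajectory
#' rule to the any-symptom indicator (count > 0) at each wave.
#'
#' @param measures A `measure_set` from [build_cross_sectional_measures()],
#'   or a `symptom_panel` (measures are built first).
#' @return A numeric matrix `n_subjects x 480` of class `pattern_matrix`,
#'   columns named `<measure>__P<k>`, with a `pattern_info` attribute
#'   (columns `column`, `measure`, `pattern`, `coding`, `n_members`).
#' @export
#' @examples
#' cohort <- cohort_preset("null", n_subjects = 20, seed = 1)
#' pm <- derive_pattern_features(build_cross_sectional_measures(cohort$panel))
#' dim(pm)  # 20 x 480
derive_pattern_features <- function(measures) {
  if (inherits(measures, "symptom_panel"))
    measures <- build_cross_sectional_measures(measures)
  stopifnot(inherits(measures, "measure_set"))
  info <- attr(measures, "measure_info")
  items <- symptom_items()$item
  n <- dim(measures)[1L]

  item_arr <- unclass(measures)[, items, , drop = FALSE]
  item_pat <- .trajectory_patterns(item_arr)           # 0/1, n x 37 each
  any_arr <- (unclass(measures) > 0) * 1               # any-symptom indicator
  any_pat <- .trajectory_patterns(any_arr)             # 0/1, n x 48 each

  n_measure <- nrow(info)
  cols <- matrix(0, nrow = n, ncol = n_measure * 10L)
  meta <- vector("list", n_measure)
  member_idx <- lapply(measure_schema()$members, function(m) match(m, items))
  for (j in seq_len(n_measure)) {
    block <- matrix(0, nrow = n, ncol = 10L)
    if (info$kind[j] == "item") {
      for (k in 1:10) block[, k] <- item_pat[[k]][, info$measure[j]]
      coding <- rep("binary", 10L)
    } else {
      mi <- member_idx[[j]]
      for (k in 1:4)
        block[, k] <- rowSums(item_pat[[k]][, mi, drop = FALSE])
      for (k in 5:10) block[, k] <- any_pat[[k]][, j]
      coding <- c(rep("continuous_count", 4L), rep("binary", 6L))
    }
    cols[, (j - 1L) * 10L + 1:10] <- block
    meta[[j]] <- data.frame(
      column = paste0(info$measure[j], "__", .PATTERNS),
      measure = info$measure[j], pattern = .PATTERNS,
      coding = coding, n_members = info$n_members[j],
      stringsAsFactors = FALSE
    )
  }
  meta <- do.call(rbind, meta)
  dimnames(cols) <- list(dimnames(measures)[[1L]], meta$column)
  structure(cols, pattern_info = meta, class = c("pattern_matrix", "matrix"))
}

#' Assemble the model design matrix
#'
#' @param patterns A `pattern_matrix` (480 trajectory predictors), required
#'   for `mode = "symptom_enhanced"` and ignored for `"non_symptom"` unless
#'   subject alignment is checked.
#' @param covariates Data frame with a `subject` column and the 35
#'   non-symptom columns of [covariate_schema()].
#' @param mode `"non_symptom"` (35 columns) or `"symptom_enhanced"`
#'   (35 + 480 = 515 columns).
#' @return Numeric matrix with a `column_info` attribute giving each
#'   column's source (`non_symptom` or `pattern`) and, for patterns, the
#'   measure/pattern/coding metadata.
#' @export
assemble_design_matrix <- function(patterns, covariates,
                                   mode = c("symptom_enhanced", "non_symptom")) {
  mode <- match.arg(mode)
  cs <- covariate_schema()
  if (!"subject" %in% names(covariates))
    stop("covariate table needs a `subject` column")
  missing_cols <- setdiff(cs$name, names(covariates))
  if (length(missing_cols))
    stop("covariate table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  subjects <- rownames(patterns)
  cov_sub <- as.character(covariates$subject)
  if (!is.null(subjects)) {
    absent <- setdiff(subjects, cov_sub)
    if (length(absent))
      stop("subject(s) in panel but not in covariate table: ",
           paste(utils::head(absent, 5L), collapse = ", "))
    extra <- setdiff(cov_sub, subjects)
    if (length(extra))
      stop("subject(s) in covariate table but not in panel: ",
           paste(utils::head(extra, 5L), collapse = ", "))
    covariates <- covariates[match(subjects, cov_sub), , drop = FALSE]
  }
  X_cov <- as.matrix(covariates[, cs$name, drop = FALSE])
  rownames(X_cov) <- subjects
  cov_info <- data.frame(
    column = cs$name, source = "non_symptom", measure = NA_character_,
    pattern = NA_character_, coding = ifelse(cs$type == "binary",
                                             "binary", "continuous"),
    stringsAsFactors = FALSE
  )
  if (mode == "non_symptom") {
    return(structure(X_cov, column_info = cov_info))
  }
  pinfo <- attr(patterns, "pattern_info")
  pat_info <- data.frame(
    column = pinfo$column, source = "pattern", measure = pinfo$measure,
    pattern = pinfo$pattern, coding = pinfo$coding, stringsAsFactors = FALSE
  )
  X <- cbind(X_cov, unclass(patterns))
  structure(X, column_info = rbind(cov_info, pat_info))
}

#' Write a pattern matrix with its column-metadata sidecar
#'
#' @param patterns A `pattern_matrix`.
#' @param path Output path for the tab-delimited matrix; the metadata
#'   sidecar is written next to it as `<path>.meta.json`.
#' @return Invisibly, the two paths written.
#' @export
write_pattern_matrix <- function(patterns, path) {
  df <- data.frame(subject = rownames(patterns),
                   unclass(patterns), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta_path <- paste0(path, ".meta.json")
  jsonlite::write_json(attr(patterns, "pattern_info"), meta_path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(c(path, meta_path))
}
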