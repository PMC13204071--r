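# The three-wave symptom panel is stored as an integer array
# [subject x item x wave] with NA marking a missing response. Items and
# waves are fixed to the canonical schema so downstream code can index by
# position.

#' Construct a three-wave symptom panel
#'
#' @param responses Integer array `n_subjects x 37 x 3` of 0/1/NA responses.
#'   Item dimnames must be the canonical item identifiers (in any order);
#'   wave dimnames must be `T1`, `T2`, `T3`.
#' @param subjects Optional subject identifiers (defaults to row dimnames or
#'   `S1..Sn`).
#' @return An object of class `symptom_panel`.
#' @export
symptom_panel <- function(responses, subjects = NULL) {
  if (length(dim(responses)) != 3L)
    stop("`responses` must be a 3-dimensional array (subject x item x wave)")
  items <- symptom_items()$item
  dn <- dimnames(responses)
  if (is.null(dn) || is.null(dn[[2L]]) || is.null(dn[[3L]]))
    stop("`responses` must carry item and wave dimnames")
  unknown <- setdiff(dn[[2L]], items)
  if (length(unknown))
    stop("unknown symptom item(s): ", paste(unknown, collapse = ", "))
  if (!setequal(dn[[2L]], items))
    stop("panel must contain all 37 canonical items; missing: ",
         paste(setdiff(items, dn[[2L]]), collapse = ", "))
  if (!identical(sort(dn[[3L]]), sort(.WAVES)))
    stop("wave labels must be exactly T1, T2, T3; got: ",
         paste(dn[[3L]], collapse = ", "))
  responses <- responses[, items, .WAVES, drop = FALSE]
  bad <- !(is.na(responses) | responses %in% c(0L, 1L))
  if (any(bad))
    stop("responses must be 0, 1 or NA")
  if (is.null(subjects)) {
    subjects <- dimnames(responses)[[1L]]
    if (is.null(subjects)) subjects <- paste0("S", seq_len(nrow(responses)))
  }
  dimnames(responses)[[1L]] <- subjects
  structure(list(responses = responses, subjects = subjects),
            class = "symptom_panel")
}

#' @export
#' @method print symptom_panel
print.symptom_panel <- function(x, ...) {
  n_miss <- sum(is.na(x$responses))
  cat(sprintf(
    "symptom_panel: %d subjects x %d items x %d waves (%d missing, %.1f%%)\n",
    length(x$subjects), dim(x$responses)[2L], dim(x$responses)[3L],
    n_miss, 100 * n_miss / length(x$responses)))
  invisible(x)
}

#' @export
#' @method dim symptom_panel
dim.symptom_panel <- function(x) dim(x$responses)

#' Convert a long-format response table to a symptom panel
#'
#' @param x Data frame with columns `subject`, `item`, `wave`, `response`
#'   (0/1, `NA` or empty for missing).
#' @return A `symptom_panel`.
#' @export
as_symptom_panel <- function(x) {
  need <- c("subject", "item", "wave", "response")
  if (!all(need %in% names(x)))
    stop("long panel needs columns: ", paste(need, collapse = ", "))
  items <- symptom_items()$item
  bad_item <- !(x$item %in% items)
  if (any(bad_item))
    stop("unknown symptom item(s) at row(s) ",
         paste(utils::head(which(bad_item), 5L), collapse = ", "), ": ",
         paste(unique(x$item[bad_item]), collapse = ", "))
  bad_wave <- !(x$wave %in% .WAVES)
  if (any(bad_wave))
    stop("unknown wave label(s) at row(s) ",
         paste(utils::head(which(bad_wave), 5L), collapse = ", "), ": ",
         paste(unique(x$wave[bad_wave]), collapse = ", "))
  subjects <- unique(as.character(x$subject))
  arr <- array(NA_integer_,
               dim = c(length(subjects), length(items), 3L),
               dimnames = list(subjects, items, .WAVES))
  idx <- cbind(match(as.character(x$subject), subjects),
               match(x$item, items),
               match(x$wave, .WAVES))
  if (anyDuplicated(idx))
    stop("duplicate (subject, item, wave) records in long panel")
  arr[idx] <- as.integer(x$response)
  symptom_panel(arr, subjects)
}

#' Convert a symptom panel to a long-format data frame
#'
#' @param panel A `symptom_panel`.
#' @return Data frame with columns `subject`, `item`, `wave`, `response`.
#' @export
panel_to_long <- function(panel) {
  stopifnot(inherits(panel, "symptom_panel"))
  d <- dim(panel$responses)
  data.frame(
    subject = rep(panel$subjects, times = d[2L] * d[3L]),
    item = rep(rep(dimnames(panel$responses)[[2L]], each = d[1L]),
               times = d[3L]),
    wave = rep(.WAVES, each = d[1L] * d[2L]),
    response = as.integer(panel$responses),
    stringsAsFactors = FALSE
  )
}

#' Fill missing symptom responses
#'
#' Missing responses are replaced with the value from the preceding wave,
#' or, if no earlier wave was observed, with the value from the nearest
#' following wave. A (subject, item) trajectory that is missing at all three
#' waves is set to absent (0) throughout, matching the predominant
#' observation in survivor cohorts. The operation is idempotent.
#'
#' @param panel A `symptom_panel`, possibly with missing responses.
#' @return A `symptom_panel` with no missing values.
#' @export
#' @examples
#' p <- cohort_preset("null", n_subjects = 5, seed = 1)$panel
#' impute_missing(p)
impute_missing <- function(panel) {
  stopifnot(inherits(panel, "symptom_panel"))
  r <- panel$responses
  # carry forward: T2 from T1, T3 from T2 (already-filled T2 propagates)
  for (w in 2:3) {
    miss <- is.na(r[, , w])
    r[, , w][miss] <- r[, , w - 1L][miss]
  }
  # carry backward for leading gaps
  for (w in 2:1) {
    miss <- is.na(r[, , w])
    r[, , w][miss] <- r[, , w + 1L][miss]
  }
  r[is.na(r)] <- 0L  # missing at every wave: considered absent
  symptom_panel(r, panel$subjects)
}
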