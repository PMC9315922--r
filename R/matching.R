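#' Exact one-to-one matching on total mutation count
#'
#' For each Low Ratio Group patient (taken in RNG-shuffled order), draws
#' uniformly without replacement one High Ratio Group patient with the
#' *identical* total mutation count. Low patients with no remaining
#' exact counterpart are recorded as unmatched and dropped from matched
#' analyses. Deterministic given `seed`.
#'
#' @param low,high Data frames with columns `patient_id` and `n_total`
#'   (all counts >= 1).
#' @param seed Integer seed controlling the shuffle and the draws.
#' @return An object of class `match_result`: list with `matched_pairs`
#'   (data.frame `low_id`, `high_id`, `n_total`), `unmatched_low`
#'   (character vector) and `seed`.
#' @examples
#' low <- data.frame(patient_id = c("l1", "l2"), n_total = c(2, 7))
#' high <- data.frame(patient_id = c("h1", "h2"), n_total = c(2, 2))
#' exact_match(low, high, seed = 1)
#' @export
exact_match <- function(low, high, seed = 1L) {
  for (tab in list(low, high)) {
    stopifnot(all(c("patient_id", "n_total") %in% names(tab)))
  }
  if (nrow(low) == 0L || nrow(high) == 0L) stop("both groups must be non-empty")
  if (any(low$n_total < 1L) || any(high$n_total < 1L)) {
    stop("matching requires n_total >= 1 for every patient")
  }
  pairs_low <- character(0)
  pairs_high <- character(0)
  pairs_n <- integer(0)
  unmatched <- character(0)
  withr::with_seed(seed, {
    pool <- split(as.character(high$patient_id), high$n_total)
    order_low <- sample.int(nrow(low))
    for (i in order_low) {
      key <- as.character(low$n_total[i])
      avail <- pool[[key]]
      if (is.null(avail) || length(avail) == 0L) {
        unmatched <- c(unmatched, as.character(low$patient_id[i]))
        next
      }
      j <- if (length(avail) == 1L) 1L else sample.int(length(avail), 1L)
      pairs_low <- c(pairs_low, as.character(low$patient_id[i]))
      pairs_high <- c(pairs_high, avail[j])
      pairs_n <- c(pairs_n, low$n_total[i])
      pool[[key]] <- avail[-j]
    }
  })
  if (length(pairs_low) == 0L) warning("empty match set: no compatible counts")
  structure(
    list(matched_pairs = data.frame(low_id = pairs_low, high_id = pairs_high,
                                    n_total = pairs_n, stringsAsFactors = FALSE),
         unmatched_low = unmatched, seed = as.integer(seed)),
    class = "match_result")
}

#' Extract burden-matched cohort tables
#'
#' Subsets a cohort table to the matched Low and High patients of a
#' [exact_match()] result. The two outputs have equal size and, by
#' construction, identical multisets of `n_total`.
#'
#' @param result A `match_result`.
#' @param cohort Cohort data frame with `patient_id` and `n_total`.
#' @return List with elements `low` and `high` (data frames, one row per
#'   matched pair, in pair order).
#' @export
matched_cohorts <- function(result, cohort) {
  stopifnot(inherits(result, "match_result"))
  mp <- result$matched_pairs
  idx_low <- match(mp$low_id, cohort$patient_id)
  idx_high <- match(mp$high_id, cohort$patient_id)
  if (anyNA(idx_low) || anyNA(idx_high)) {
    stop("matched patient id(s) absent from cohort table")
  }
  low <- cohort[idx_low, , drop = FALSE]
  high <- cohort[idx_high, , drop = FALSE]
  rownames(low) <- rownames(high) <- NULL
  if (length(result$unmatched_low)) {
    message(length(result$unmatched_low),
            " Low Ratio patient(s) had no exact-count counterpart and were dropped")
  }
  list(low = low, high = high)
}

#' @export
print.match_result <- function(x, ...) {
  cat("Exact match on total mutation count\n")
  cat("  matched pairs :", nrow(x$matched_pairs), "\n")
  cat("  unmatched low :", length(x$unmatched_low), "\n")
  cat("  seed          :", x$seed, "\n")
  invisible(x)
}
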