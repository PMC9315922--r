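#' Parameters for the (S+Rc)/Rnc mutation-type ratio
#'
#' Two pseudocounts are in play, kept independently configurable because
#' they serve different equations: `group_pseudocount` (default 0.05)
#' enters the grouping ratio `(S + Rc + 0.05) / (Rnc + 0.05)`, while
#' `cox_pseudocount` (default 0.5) enters the log-ratio covariate
#' `ln((S + Rc + 0.5) / (Rnc + 0.5))` used in the two-variable Cox
#' model. Sequences with ratio <= `ratio_threshold` (default 1.0) form
#' the Low Ratio Group, those above it the High Ratio Group; with
#' `threshold_mode = "median"` the threshold is recomputed as the sample
#' median ratio over sequences with at least one mutation.
#'
#' @param group_pseudocount,cox_pseudocount Positive pseudocounts.
#' @param ratio_threshold Positive group boundary (boundary itself is Low).
#' @param threshold_mode `"fixed"` or `"median"`.
#' @return A list of class `ratio_params`.
#' @export
ratio_params <- function(group_pseudocount = 0.05, cox_pseudocount = 0.5,
                         ratio_threshold = 1.0,
                         threshold_mode = c("fixed", "median")) {
  threshold_mode <- match.arg(threshold_mode)
  if (group_pseudocount <= 0 || cox_pseudocount <= 0) {
    stop("pseudocounts must be positive")
  }
  if (ratio_threshold <= 0) stop("ratio_threshold must be positive")
  structure(list(group_pseudocount = group_pseudocount,
                 cox_pseudocount = cox_pseudocount,
                 ratio_threshold = ratio_threshold,
                 threshold_mode = threshold_mode),
            class = "ratio_params")
}

#' Compute pseudocounted mutation-type ratios
#'
#' For each profile, `ratio = (n_s + n_rc + c) / (n_rnc + c)` with
#' `c = group_pseudocount`, and `log_ratio = ln((n_s + n_rc + c') /
#' (n_rnc + c'))` with `c' = cox_pseudocount`. For sequences with no
#' somatic mutation the ratio is not defined: `ratio`, `log_ratio` and
#' `ratio_group` are `NA` and such sequences are excluded from ratio
#' analyses. Group assignment uses the *fixed* threshold here; use
#' [assign_groups()] for median-threshold cohort labelling.
#'
#' @param profiles Data frame with integer columns `n_s`, `n_rc`,
#'   `n_rnc`, `n_total` (e.g. from [profile_sequence()]).
#' @param params A [ratio_params()] object.
#' @return `profiles` with added `ratio`, `log_ratio`, `ratio_group`
#'   (`"low"`, `"high"` or `NA`).
#' @examples
#' p <- data.frame(n_s = c(3, 0, 6, 0), n_rc = c(2, 0, 0, 0),
#'                 n_rnc = c(5, 4, 0, 0))
#' p$n_total <- p$n_s + p$n_rc + p$n_rnc
#' compute_ratio(p)[, c("ratio", "ratio_group")]
#' @export
compute_ratio <- function(profiles, params = ratio_params()) {
  stopifnot(all(c("n_s", "n_rc", "n_rnc", "n_total") %in% names(profiles)))
  if (any(profiles$n_s < 0 | profiles$n_rc < 0 | profiles$n_rnc < 0)) {
    stop("negative mutation counts")
  }
  c1 <- params$group_pseudocount
  c2 <- params$cox_pseudocount
  defined <- profiles$n_total >= 1L
  ratio <- ifelse(defined,
                  (profiles$n_s + profiles$n_rc + c1) / (profiles$n_rnc + c1),
                  NA_real_)
  log_ratio <- ifelse(defined,
                      log((profiles$n_s + profiles$n_rc + c2) /
                            (profiles$n_rnc + c2)),
                      NA_real_)
  group <- ifelse(defined,
                  ifelse(ratio <= params$ratio_threshold, "low", "high"),
                  NA_character_)
  out <- profiles
  out$ratio <- ratio
  out$log_ratio <- log_ratio
  out$ratio_group <- group
  out
}

#' Assign Low/High Ratio Groups across a cohort
#'
#' Computes ratios with [compute_ratio()] and labels every sequence with
#' at least one mutation as `"low"` (ratio <= threshold) or `"high"`
#' (ratio > threshold). Under `threshold_mode = "median"` the threshold
#' is the sample median of the ratios of mutated sequences. Zero-mutation
#' sequences keep `NA` (ratio undefined).
#'
#' @inheritParams compute_ratio
#' @return Annotated data frame; the threshold actually used is attached
#'   as `attr(, "ratio_threshold")` and group sizes as `attr(, "group_sizes")`.
#' @export
assign_groups <- function(profiles, params = ratio_params()) {
  out <- compute_ratio(profiles, params)
  defined <- !is.na(out$ratio)
  if (!any(defined)) stop("no sequence with >= 1 mutation: ratio groups undefined")
  threshold <- params$ratio_threshold
  if (params$threshold_mode == "median") {
    threshold <- stats::median(out$ratio[defined])
  }
  out$ratio_group[defined] <- ifelse(out$ratio[defined] <= threshold,
                                     "low", "high")
  sizes <- c(low = sum(out$ratio_group == "low", na.rm = TRUE),
             high = sum(out$ratio_group == "high", na.rm = TRUE))
  if (any(sizes == 0L)) {
    warning("empty ratio group: ", paste(names(sizes)[sizes == 0L], collapse = ", "))
  }
  attr(out, "ratio_threshold") <- threshold
  attr(out, "group_sizes") <- sizes
  out
}

#' Default mutation-count bin scheme
#'
#' The intervals used for burden-stratified TTFT comparisons: `{0}`,
#' `1-4`, `5-6`, `7-9`, `10-12`, `13-15`, `16-18`, `19-21`, `>21`
#' (implemented as `[22, Inf)` on integer counts). Zero-mutation
#' patients are kept in their own bin for comparison.
#'
#' @return Data frame with `lower`, `upper`, `label`.
#' @export
default_bin_scheme <- function() {
  data.frame(
    lower = c(0L, 1L, 5L, 7L, 10L, 13L, 16L, 19L, 22L),
    upper = c(0L, 4L, 6L, 9L, 12L, 15L, 18L, 21L, Inf),
    label = c("0", "1-4", "5-6", "7-9", "10-12", "13-15", "16-18", "19-21", ">21"),
    stringsAsFactors = FALSE)
}

#' Bin patients by total mutation count
#'
#' @param n_total Integer vector of total mutation counts.
#' @param scheme A bin scheme as from [default_bin_scheme()]; intervals
#'   must be disjoint and exhaustive over the non-negative integers.
#' @return Factor with one level per bin, in scheme order.
#' @examples
#' bin_by_mutation_count(c(0, 5, 36))
#' @export
bin_by_mutation_count <- function(n_total, scheme = default_bin_scheme()) {
  if (any(n_total < 0, na.rm = TRUE)) stop("negative mutation counts")
  if (any(scheme$lower[-1] != head(scheme$upper, -1) + 1L)) {
    stop("bin scheme intervals must be disjoint and exhaustive")
  }
  idx <- findInterval(n_total, scheme$lower)
  factor(scheme$label[idx], levels = scheme$label)
}
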