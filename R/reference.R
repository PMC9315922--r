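#' Reference cohort mutation-type category counts
#'
#' Published per-consortium counts of the four mutation-composition
#' categories (no mutations; silent-only; replacement-only; silent +
#' replacement) in a large two-consortium CLL cohort (n = 3,598): one
#' column per contributing consortium. Shipped as a plain CSV so the
#' cohort accounting arithmetic can be recomputed and audited.
#'
#' @return Data frame with columns `category`, `crc`, `eric`.
#' @export
reference_cohort_counts <- function() {
  path <- system.file("extdata", "reference_cohort_counts.csv",
                      package = "ighvratio")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute category percentages and combined counts
#'
#' Given per-group category counts, derives each group's total, the
#' combined counts across groups, and the percentage of every category
#' within its group (rounded to `digits` decimals, matching the usual
#' reporting precision).
#'
#' @param counts Data frame: `category` column plus one integer column
#'   per group (default [reference_cohort_counts()]).
#' @param digits Rounding for the percentage columns (default 1).
#' @return Data frame with, per group `g`, columns `g` (count) and
#'   `g_pct`, plus `combined` and `combined_pct`; attribute `totals`
#'   holds the per-group totals.
#' @examples
#' cohort_category_summary()
#' @export
cohort_category_summary <- function(counts = reference_cohort_counts(),
                                    digits = 1) {
  stopifnot("category" %in% names(counts))
  groups <- setdiff(names(counts), "category")
  out <- data.frame(category = counts$category, stringsAsFactors = FALSE)
  totals <- numeric(0)
  combined <- rep(0, nrow(counts))
  for (g in groups) {
    x <- counts[[g]]
    if (any(x < 0)) stop("negative counts")
    tot <- sum(x)
    totals[g] <- tot
    out[[g]] <- x
    out[[paste0(g, "_pct")]] <- round(100 * x / tot, digits)
    combined <- combined + x
  }
  out$combined <- combined
  out$combined_pct <- round(100 * combined / sum(combined), digits)
  totals["combined"] <- sum(combined)
  attr(out, "totals") <- totals
  out
}
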