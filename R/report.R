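#' Stratified TTFT report: KM curves, medians and pairwise log-rank
#'
#' Summarises time-to-first-treatment across the strata of a cohort
#' column — the standard comparisons being mutation status (< 2% vs
#' >= 2%), ratio group (low vs high), status within one ratio group,
#' ratio group within one status, or mutation-count bins. Strata with no
#' patients are omitted with a warning. P-values are nominal, without
#' multiplicity adjustment.
#'
#' @param cohort Cohort data frame with `ttft_years`, `event` and the
#'   stratifying column.
#' @param by Name of the stratifying column (e.g. `"status"`,
#'   `"ratio_group"`, `"mutation_bin"`).
#' @param subset Optional logical vector selecting cohort rows first
#'   (e.g. `cohort$ratio_group == "low"` for within-group comparisons).
#' @return List of class `ttft_report`: `strata` (data.frame with
#'   `stratum`, `n`, `n_treated`, `median_ttft`), `curves` (named list
#'   of `km_curve`), `pairwise` (from [pairwise_logrank()], NULL if a
#'   single stratum), `by`.
#' @export
ttft_report <- function(cohort, by, subset = NULL) {
  stopifnot(by %in% names(cohort))
  if (!is.null(subset)) cohort <- cohort[which(subset), , drop = FALSE]
  keep <- !is.na(cohort[[by]]) & !is.na(cohort$ttft_years) & !is.na(cohort$event)
  cohort <- cohort[keep, , drop = FALSE]
  if (nrow(cohort) == 0L) stop("no patients to report on")
  g <- as.character(cohort[[by]])
  all_levs <- if (is.factor(cohort[[by]])) levels(cohort[[by]]) else unique(g)
  levs <- intersect(all_levs, unique(g))
  dropped <- setdiff(all_levs, levs)
  if (length(dropped)) warning("empty strata omitted: ",
                               paste(dropped, collapse = ", "))
  curves <- list()
  rows <- list()
  for (lv in levs) {
    sel <- g == lv
    km <- km_fit(cohort$ttft_years[sel], cohort$event[sel])
    curves[[lv]] <- km
    rows[[lv]] <- data.frame(stratum = lv, n = km$n, n_treated = km$n_events,
                             median_ttft = km$median, stringsAsFactors = FALSE)
  }
  strata <- do.call(rbind, rows)
  rownames(strata) <- NULL
  pairwise <- NULL
  if (length(levs) >= 2L && sum(cohort$event) > 0L) {
    pairwise <- pairwise_logrank(cohort$ttft_years, cohort$event, g)
  }
  structure(list(strata = strata, curves = curves, pairwise = pairwise, by = by),
            class = "ttft_report")
}

#' Display-format a p-value
#'
#' Nominal p-values below 1e-4 are floored in display as `"< 0.0001"`;
#' raw values stay available in machine output.
#'
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 1e-4, "< 0.0001", sprintf("%.4g", p)))
}

#' @export
print.ttft_report <- function(x, ...) {
  cat("TTFT report stratified by", x$by, "\n")
  tab <- x$strata
  tab$median_ttft <- ifelse(is.na(tab$median_ttft), "not reached",
                            sprintf("%.2f years", tab$median_ttft))
  print(tab, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("pairwise log-rank p-values (nominal):\n")
    print(apply(x$pairwise$p_value, c(1, 2), format_p), quote = FALSE)
  }
  invisible(x)
}

#' Write the tables of a TTFT report to disk
#'
#' Emits one KM curve TSV (`time`, `n_risk`, `n_event`, `n_censor`,
#' `surv`, `stratum`) and a JSON file with strata summaries and pairwise
#' log-rank results.
#'
#' @param report A `ttft_report`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default the stratifying column.
#' @return Invisible character vector of file paths.
#' @export
write_ttft_report <- function(report, dir, prefix = report$by) {
  stopifnot(inherits(report, "ttft_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  km_tab <- do.call(rbind, lapply(names(report$curves), function(lv) {
    cbind(report$curves[[lv]]$table, stratum = lv)
  }))
  km_path <- file.path(dir, paste0(prefix, "_km.tsv"))
  utils::write.table(km_tab, km_path, sep = "\t", row.names = FALSE, quote = FALSE)
  js <- list(strata = report$strata)
  if (!is.null(report$pairwise)) {
    js$pairwise_logrank <- list(
      chi_square = report$pairwise$chi_square,
      p_value = report$pairwise$p_value,
      p_display = apply(report$pairwise$p_value, c(1, 2), format_p))
  }
  js_path <- file.path(dir, paste0(prefix, "_tests.json"))
  jsonlite::write_json(js, js_path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor", pretty = TRUE)
  invisible(c(km_path, js_path))
}
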