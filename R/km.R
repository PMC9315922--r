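#' Kaplan-Meier product-limit estimator
#'
#' From-first-principles product-limit estimate of the survival (here:
#' untreated) function. Censored observations decrement the risk set
#' without dropping the curve. The median is the smallest time at which
#' the estimate falls to 0.5 or below, and is `NA` when the curve never
#' reaches 0.5 (common in long-TTFT strata).
#'
#' @param time Positive event/censoring times (years).
#' @param event Logical (or 0/1): TRUE = event (treated), FALSE = censored.
#' @return Object of class `km_curve`: list with `table` (data.frame
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv` over distinct
#'   observed times), `median`, `n`, `n_events`.
#' @examples
#' km <- km_fit(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))
#' km$table$surv    # 0.75 0.50 0.25 0.00
#' km$median        # 2
#' @export
km_fit <- function(time, event) {
  event <- as.logical(event)
  if (length(time) == 0L) stop("no samples")
  if (any(is.na(time)) || any(is.na(event))) stop("missing time or event values")
  if (any(time <= 0)) stop("times must be positive")
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- unique(time)
  n <- length(time)
  d <- vapply(ut, function(t) sum(time == t & event), numeric(1))
  cns <- vapply(ut, function(t) sum(time == t & !event), numeric(1))
  n_risk <- n - c(0, cumsum(d + cns))[seq_along(ut)]
  surv <- cumprod(1 - d / n_risk)
  tab <- data.frame(time = ut, n_risk = n_risk, n_event = d, n_censor = cns,
                    surv = surv)
  med <- km_median(tab)
  structure(list(table = tab, median = med, n = n, n_events = sum(event)),
            class = "km_curve")
}

#' Median survival time of a KM curve
#'
#' @param x A `km_curve` or its `table` data.frame.
#' @return Smallest time with survival <= 0.5, or `NA` if never reached.
#' @export
km_median <- function(x) {
  tab <- if (inherits(x, "km_curve")) x$table else x
  hit <- which(tab$surv <= 0.5 + 1e-12)
  if (length(hit) == 0L) NA_real_ else tab$time[hit[1]]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s\n",
              x$n, x$n_events,
              if (is.na(x$median)) "not reached" else sprintf("%.2f", x$median)))
  invisible(x)
}

#' Two-sample log-rank (Mantel-Cox) test
#'
#' Observed-vs-expected events with the hypergeometric variance at each
#' distinct event time; the statistic is referred to chi-square with one
#' degree of freedom. Identical groups give statistic 0 and p = 1.
#'
#' @param time,event Pooled times and event indicators.
#' @param group Two-level grouping vector aligned with `time`.
#' @return List with `chi_square`, `p_value`, `observed`, `expected`
#'   (both per group, named).
#' @export
logrank_test <- function(time, event, group) {
  event <- as.logical(event)
  if (any(time <= 0)) stop("times must be positive")
  group <- as.character(group)
  levs <- unique(group)
  if (length(levs) != 2L) stop("logrank_test requires exactly two groups")
  if (sum(event) == 0L) stop("no events in either group")
  g1 <- group == levs[1]
  ut <- sort(unique(time[event]))
  o1 <- e1 <- v <- 0
  for (t in ut) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    n1j <- sum(at_risk & g1)
    dj <- sum(time == t & event)
    d1j <- sum(time == t & event & g1)
    o1 <- o1 + d1j
    e1 <- e1 + dj * n1j / nj
    if (nj > 1) {
      v <- v + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    }
  }
  chi <- if (v > 0) (o1 - e1)^2 / v else 0
  o <- c(o1, sum(event) - o1)
  e <- c(e1, sum(event) - e1)
  names(o) <- names(e) <- levs
  list(chi_square = chi, p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       observed = o, expected = e)
}

#' Pairwise log-rank tests over k strata
#'
#' Runs [logrank_test()] on every pair of strata and returns nominal
#' (unadjusted) p-values, following the convention of reporting nominal
#' p-values without multiplicity correction.
#'
#' @inheritParams logrank_test
#' @param group Grouping vector with two or more levels.
#' @return List with matrices `chi_square` and `p_value` (strata x strata,
#'   upper and lower triangles filled, diagonal NA).
#' @export
pairwise_logrank <- function(time, event, group) {
  group <- as.character(group)
  levs <- unique(group)
  k <- length(levs)
  if (k < 2L) stop("need at least two groups")
  chi <- p <- matrix(NA_real_, k, k, dimnames = list(levs, levs))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      sel <- group %in% c(levs[i], levs[j])
      if (sum(event[sel]) == 0L) next
      lr <- logrank_test(time[sel], event[sel], group[sel])
      chi[i, j] <- chi[j, i] <- lr$chi_square
      p[i, j] <- p[j, i] <- lr$p_value
    }
  }
  list(chi_square = chi, p_value = p)
}
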