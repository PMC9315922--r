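#' Configuration for the synthetic cohort generator
#'
#' The defaults encode the cohort structure the analysis assumes:
#' about 35% of clones carry no IGHV mutation; mutated clones carry 1-36
#' nucleotide substitutions with a burden distribution proportional to
#' the observed sizes of the standard mutation-count bins (1-4, 5-6,
#' 7-9, 10-12, 13-15, 16-18, 19-21, >21), uniform within a bin;
#' substitutions favour transitions 2:1 over each transversion; event
#' times follow a Weibull baseline (shape `k = 1`, i.e. exponential, and
#' scale 8 years) with log-hazard `beta_mut * n_total + beta_group *
#' 1[high ratio group]`, so the treatment hazard decreases with mutation
#' burden for `beta_mut < 0`; censoring combines an independent
#' exponential rate with an administrative cutoff.
#'
#' @param n_patients Number of patients.
#' @param p_zero_mut Probability of a zero-mutation clone (default 0.35).
#' @param burden_pmf Probability mass over counts 1..36 for mutated
#'   clones (default [default_burden_pmf()]).
#' @param ts_weight Relative weight of the transition alternative versus
#'   each transversion (default 2).
#' @param hotspot_multiplier Position-weight multiplier inside WRC/GYW
#'   hotspot motifs (default 1 = off).
#' @param shape,scale Weibull baseline shape and scale (years).
#' @param beta_mut Log-hazard per additional mutation (default -0.05).
#' @param beta_group Log-hazard of high vs low ratio group (default 0).
#' @param censor_rate Exponential censoring rate per year (default 0.02).
#' @param admin_censor_years Administrative cutoff (default 25).
#' @param n_germline,germline_length Germline reference pool.
#' @param target_high_frac Optional. By default (`NULL`) the S/Rc/Rnc
#'   composition — and hence the Low/High split — is *emergent* from
#'   random substitutions plus the classifier, which under neutral
#'   substitution leaves the High group small. Setting a fraction in
#'   (0, 1) turns on per-patient rejection sampling of the mutation set
#'   (burden unchanged) so that about that fraction of mutated clones
#'   lands in the High group, for studies that need both groups
#'   populated.
#' @param seed Master seed; all randomness derives from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_patients = 500L, p_zero_mut = 0.35,
                       burden_pmf = default_burden_pmf(), ts_weight = 2,
                       hotspot_multiplier = 1, shape = 1, scale = 8,
                       beta_mut = -0.05, beta_group = 0, censor_rate = 0.02,
                       admin_censor_years = 25, n_germline = 5L,
                       germline_length = 300L, target_high_frac = NULL,
                       seed = 1L) {
  stopifnot(n_patients >= 1L, p_zero_mut >= 0, p_zero_mut <= 1,
            ts_weight > 0, hotspot_multiplier >= 1, shape > 0, scale > 0,
            censor_rate >= 0, admin_censor_years > 0,
            germline_length %% 3L == 0L)
  if (length(burden_pmf) != 36L || any(burden_pmf < 0)) {
    stop("burden_pmf must be a non-negative vector over counts 1..36")
  }
  if (abs(sum(burden_pmf) - 1) > 1e-8) stop("burden_pmf must sum to 1")
  if (!is.null(target_high_frac) &&
      (target_high_frac <= 0 || target_high_frac >= 1)) {
    stop("target_high_frac must be in (0, 1) or NULL")
  }
  structure(list(n_patients = as.integer(n_patients), p_zero_mut = p_zero_mut,
                 burden_pmf = burden_pmf, ts_weight = ts_weight,
                 hotspot_multiplier = hotspot_multiplier, shape = shape,
                 scale = scale, beta_mut = beta_mut, beta_group = beta_group,
                 censor_rate = censor_rate,
                 admin_censor_years = admin_censor_years,
                 n_germline = as.integer(n_germline),
                 germline_length = as.integer(germline_length),
                 target_high_frac = target_high_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default mutation-burden distribution over 1..36
#'
#' Probability mass proportional to the relative sizes of the standard
#' mutation-count bins (389, 173, 232, 221, 257, 297, 240 and 539
#' patients for 1-4, 5-6, 7-9, 10-12, 13-15, 16-18, 19-21 and >21),
#' spread uniformly over the integer counts within each bin; the open
#' top bin is truncated at 36, the largest per-sequence count the
#' analysis is designed around.
#'
#' @return Numeric vector of length 36 summing to 1.
#' @export
default_burden_pmf <- function() {
  bins <- data.frame(lower = c(1, 5, 7, 10, 13, 16, 19, 22),
                     upper = c(4, 6, 9, 12, 15, 18, 21, 36),
                     size = c(389, 173, 232, 221, 257, 297, 240, 539))
  pmf <- numeric(36)
  for (i in seq_len(nrow(bins))) {
    idx <- bins$lower[i]:bins$upper[i]
    pmf[idx] <- bins$size[i] / length(idx)
  }
  pmf / sum(pmf)
}

#' Draw per-patient mutation burdens
#'
#' Zero with probability `p_zero_mut`, otherwise a count from
#' `burden_pmf` over 1..36. Uses the current RNG state.
#'
#' @param n Number of patients.
#' @param config A [sim_config()].
#' @return Integer vector of length `n`.
#' @export
draw_mutation_burden <- function(n, config = sim_config()) {
  zero <- stats::rbinom(n, 1L, config$p_zero_mut) == 1L
  out <- integer(n)
  k <- sum(!zero)
  if (k > 0L) out[!zero] <- sample.int(36L, k, replace = TRUE,
                                       prob = config$burden_pmf)
  out
}

#' Generate stop-free germline reference sequences
#'
#' Random in-frame sequences built from the 61 sense codons, so no
#' reading frame 0 stop codons occur; reproducible given `seed`.
#'
#' @param n_genes Number of germline genes.
#' @param length_nt Sequence length, divisible by 3 (default 300).
#' @param seed Integer seed.
#' @return Named character vector; names follow `IGHVS1-<i>*01`
#'   (synthetic gene names).
#' @export
make_germline <- function(n_genes, length_nt = 300L, seed = 1L) {
  if (length_nt %% 3L != 0L) stop("length_nt must be divisible by 3")
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n_genes), function(i) {
      paste(sample(sense, length_nt %/% 3L, replace = TRUE), collapse = "")
    }, character(1))
  })
  names(seqs) <- sprintf("IGHVS1-%d*01", seq_len(n_genes))
  seqs
}

# add codon context (frame offset 0, no gaps) to a simulator site list
.annotate_codons <- function(sites, germline_seq) {
  if (nrow(sites) == 0L) return(sites)
  rel <- sites$position - 1L
  ci <- rel %/% 3L
  sites$pos_in_codon <- rel %% 3L
  sites$germline_codon <- substring(germline_seq, 3L * ci + 1L, 3L * ci + 3L)
  sites$observed_base <- sites$to
  sites
}

# alignment-free hotspot scan: WRC (W=A/T, R=A/G) position of C,
# GYW position of G
.hotspot_positions <- function(chars) {
  L <- length(chars)
  hot <- logical(L)
  if (L >= 3L) {
    w <- chars %in% c("A", "T")
    r <- chars %in% c("A", "G")
    y <- chars %in% c("C", "T")
    is_c <- chars == "C"
    is_g <- chars == "G"
    i <- 3:L
    hot[i] <- hot[i] | (w[i - 2L] & r[i - 1L] & is_c[i])
    j <- 1:(L - 2L)
    hot[j] <- hot[j] | (is_g[j] & y[j + 1L] & w[j + 2L])
  }
  hot
}

#' Introduce somatic point mutations into a germline sequence
#'
#' Samples `n_mut` distinct positions (weighted by `hotspot_multiplier`
#' inside WRC/GYW motifs of the germline) and substitutes each base,
#' choosing the transition with weight `ts_weight` and each transversion
#' with weight 1. No indels are introduced. Uses the current RNG state
#' unless `seed` is given.
#'
#' @param germline Germline DNA string (unambiguous `A C G T`).
#' @param n_mut Number of substitutions (0 allowed; must not exceed the
#'   sequence length).
#' @param ts_weight,hotspot_multiplier See [sim_config()].
#' @param seed Optional seed for standalone reproducibility.
#' @return List with `sequence` (mutated string) and `sites`
#'   (data.frame `position` 1-based, `from`, `to`).
#' @export
mutate_sequence <- function(germline, n_mut, ts_weight = 2,
                            hotspot_multiplier = 1, seed = NULL) {
  run <- function() {
    chars <- strsplit(germline, "", fixed = TRUE)[[1]]
    L <- length(chars)
    if (n_mut > L) stop("n_mut exceeds sequence length")
    if (!all(chars %in% DNA_BASES_STRICT)) {
      stop("germline must be unambiguous A/C/G/T")
    }
    if (n_mut == 0L) {
      return(list(sequence = germline,
                  sites = data.frame(position = integer(0), from = character(0),
                                     to = character(0), stringsAsFactors = FALSE)))
    }
    wts <- rep(1, L)
    wts[.hotspot_positions(chars)] <- hotspot_multiplier
    pos <- sort(sample.int(L, n_mut, replace = FALSE, prob = wts))
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    to <- character(n_mut)
    for (i in seq_len(n_mut)) {
      from <- chars[pos[i]]
      alts <- setdiff(DNA_BASES_STRICT, from)
      w <- ifelse(alts == transition[[from]], ts_weight, 1)
      to[i] <- alts[sample.int(3L, 1L, prob = w)]
    }
    chars[pos] <- to
    list(sequence = paste(chars, collapse = ""),
         sites = data.frame(position = pos,
                            from = strsplit(germline, "", fixed = TRUE)[[1]][pos],
                            to = to, stringsAsFactors = FALSE))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a synthetic CLL cohort end-to-end
#'
#' Generates germline references, per-patient mutated rearrangements
#' (emitted as pre-aligned pairs, no indels), censored TTFT, and a truth
#' table holding the generator's own S/Rc/Rnc accounting (computed with
#' the same class tables the pipeline uses, so end-to-end recovery is
#' exact by construction). Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `simulated_cohort`: list with `germline`
#'   (named character vector), `rearrangements` (AIRR-style data.frame),
#'   `clinical` (data.frame `patient_id`, `ttft_years`, `event`),
#'   `truth` (per-patient true counts, ratio, group, linear predictor)
#'   and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  germ <- make_germline(config$n_germline, config$germline_length,
                        seed = config$seed)
  n <- config$n_patients
  withr::with_seed(config$seed + 1L, {
    burden <- draw_mutation_burden(n, config)
    gene_idx <- sample.int(config$n_germline, n, replace = TRUE)
    pid <- sprintf("pt%05d", seq_len(n))
    seqs <- character(n)
    all_sites <- vector("list", n)
    thf <- config$target_high_frac
    want_high <- if (is.null(thf)) rep(NA, n) else stats::runif(n) < thf
    for (i in seq_len(n)) {
      g <- germ[[gene_idx[i]]]
      draw <- function() mutate_sequence(
        g, burden[i], ts_weight = config$ts_weight,
        hotspot_multiplier = config$hotspot_multiplier)
      mut <- draw()
      if (!is.null(thf) && burden[i] >= 1L) {
        # rejection-sample the mutation set (same burden) toward the
        # desired ratio group
        for (attempt in seq_len(100L)) {
          cls_i <- classify_sites(.annotate_codons(mut$sites, g))
          cnt <- table(factor(cls_i$label, levels = c("S", "Rc", "Rnc")))
          r <- (cnt[["S"]] + cnt[["Rc"]] + 0.05) / (cnt[["Rnc"]] + 0.05)
          if ((r > 1) == want_high[i]) break
          mut <- draw()
        }
      }
      seqs[i] <- mut$sequence
      if (nrow(mut$sites)) {
        st <- .annotate_codons(mut$sites, g)
        st$patient_id <- pid[i]
        all_sites[[i]] <- st
      }
    }
    sites <- do.call(rbind, all_sites)

    counts <- data.frame(patient_id = pid, n_s = 0L, n_rc = 0L, n_rnc = 0L,
                         stringsAsFactors = FALSE)
    if (!is.null(sites) && nrow(sites)) {
      cls <- classify_sites(sites)
      for (lab in c("S", "Rc", "Rnc")) {
        tab <- table(factor(cls$patient_id[cls$label == lab], levels = pid))
        col <- c(S = "n_s", Rc = "n_rc", Rnc = "n_rnc")[[lab]]
        counts[[col]] <- as.integer(tab)
      }
    }
    counts$n_total <- counts$n_s + counts$n_rc + counts$n_rnc
    stopifnot(identical(counts$n_total, as.integer(burden)))
    counts <- compute_ratio(counts)

    is_high <- !is.na(counts$ratio_group) & counts$ratio_group == "high"
    eta <- config$beta_mut * counts$n_total + config$beta_group * is_high
    u <- stats::runif(n)
    t_event <- config$scale * (-log(u) / exp(eta))^(1 / config$shape)
    c_rand <- if (config$censor_rate > 0) {
      stats::rexp(n, rate = config$censor_rate)
    } else rep(Inf, n)
    t_cens <- pmin(c_rand, config$admin_censor_years)
    time <- pmax(pmin(t_event, t_cens), 1e-6)
    event <- t_event <= t_cens
  })

  v_call <- names(germ)[gene_idx]
  rearr <- data.frame(
    sequence_id = pid, sequence = seqs, sequence_alignment = seqs,
    germline_alignment = unname(germ[gene_idx]), v_call = v_call,
    stringsAsFactors = FALSE)
  clinical <- data.frame(patient_id = pid, ttft_years = time, event = event,
                         stringsAsFactors = FALSE)
  truth <- counts
  truth$v_call <- v_call
  truth$eta <- eta
  truth$event_time_true <- t_event
  structure(list(germline = germ, rearrangements = rearr, clinical = clinical,
                 truth = truth, config = config),
            class = "simulated_cohort")
}

#' Write a simulated cohort to disk in pipeline input formats
#'
#' Emits `germline.fasta`, `rearrangements.tsv` (AIRR-style),
#' `clinical.csv` and `truth.csv` into `dir`.
#'
#' @param cohort A `simulated_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisible named character vector of file paths.
#' @export
write_simulated_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(germline = file.path(dir, "germline.fasta"),
             rearrangements = file.path(dir, "rearrangements.tsv"),
             clinical = file.path(dir, "clinical.csv"),
             truth = file.path(dir, "truth.csv"))
  gs <- Biostrings::DNAStringSet(cohort$germline)
  Biostrings::writeXStringSet(gs, paths[["germline"]])
  utils::write.table(cohort$rearrangements, paths[["rearrangements"]],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  clin <- cohort$clinical
  clin$ttft_years <- sprintf("%.17g", clin$ttft_years)
  clin$event <- tolower(as.character(clin$event))
  utils::write.csv(clin, paths[["clinical"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
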