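#' Align a patient rearrangement to its germline gene
#'
#' Produces an aligned patient/germline pair for mutation calling. If
#' the two sequences already have equal length (the pre-aligned,
#' IMGT-gapped case) they are passed through unchanged; otherwise gaps
#' are stripped and a global (Needleman-Wunsch) alignment is computed
#' with match +2, mismatch -1, gap open -6, gap extend -1. Alignment
#' columns where either character is not an unambiguous base (`A C G T`)
#' are excluded from `compared_length`.
#'
#' @param patient,germline Either plain DNA strings or single-row
#'   records with `id`/`nt_sequence` fields (as from [read_fasta()]).
#' @param patient_id Identifier stored on the pair (defaults to the
#'   patient record id when available).
#' @param frame_offset Reading-frame offset of the *germline* sequence
#'   (0, 1 or 2); codon coordinates are derived from it.
#' @param min_overlap Minimum number of compared positions; fewer
#'   triggers an "insufficient overlap" error.
#' @return An object of class `germline_pair`: a list with
#'   `patient_id`, `aligned_patient`, `aligned_germline`,
#'   `frame_offset`, `compared_length`.
#' @examples
#' p <- align_pair("ATGCCA", "ATGCGA", patient_id = "pt1", min_overlap = 1)
#' p$compared_length
#' call_mutations(p)
#' @export
align_pair <- function(patient, germline, patient_id = NULL, frame_offset = 0L,
                       min_overlap = 60L) {
  pseq <- .coerce_seq(patient)
  gseq <- .coerce_seq(germline)
  if (is.null(patient_id)) patient_id <- attr(pseq, "id") %||% ""
  if (!nzchar(pseq)) stop("empty patient sequence")
  if (!nzchar(gseq)) stop("empty germline sequence")
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")

  if (nchar(pseq) == nchar(gseq)) {
    ap <- pseq
    ag <- gseq
  } else {
    pd <- gsub("[.\\-]", "", pseq)
    gd <- gsub("[.\\-]", "", gseq)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                    baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(pd),
      subject = Biostrings::DNAStringSet(gd)[[1]],
      type = "global", substitutionMatrix = mat,
      gapOpening = 6, gapExtension = 1)
    ap <- as.character(Biostrings::alignedPattern(aln))
    ag <- as.character(Biostrings::alignedSubject(aln))
  }
  pc <- strsplit(ap, "", fixed = TRUE)[[1]]
  gc_ <- strsplit(ag, "", fixed = TRUE)[[1]]
  compared <- sum(pc %in% DNA_BASES_STRICT & gc_ %in% DNA_BASES_STRICT)
  if (compared < min_overlap) {
    stop(sprintf("insufficient overlap: %d compared positions (< %d)",
                 compared, min_overlap))
  }
  structure(
    list(patient_id = patient_id, aligned_patient = ap, aligned_germline = ag,
         frame_offset = as.integer(frame_offset),
         compared_length = as.integer(compared)),
    class = "germline_pair")
}

.coerce_seq <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x))) {
    return(toupper(x))
  }
  if (is.data.frame(x)) x <- as.list(x[1, , drop = FALSE])
  if (is.list(x) && !is.null(x$nt_sequence)) {
    out <- toupper(x$nt_sequence)
    attr(out, "id") <- x$id %||% ""
    return(out)
  }
  if (is.character(x) && length(x) == 1L) {
    out <- toupper(unname(x))
    attr(out, "id") <- names(x)
    return(out)
  }
  stop("cannot interpret sequence input")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate nucleotide mutations in an aligned pair
#'
#' Reports every alignment column where patient and germline both carry
#' an unambiguous base (`A C G T`) and the bases differ. Indels (gap
#' columns) and `N`-masked columns are never counted. Codon context is
#' computed on germline coordinates from the pair's `frame_offset`; the
#' `observed_codon` holds the patient characters over the germline
#' codon's columns (NA when interrupted by an indel), while isolated
#' single-base effects are derived from `germline_codon` downstream.
#'
#' @param pair A `germline_pair` from [align_pair()].
#' @return A data.frame of mutation sites, sorted by `alignment_pos`
#'   (0-based), with columns `patient_id`, `alignment_pos`,
#'   `germline_base`, `observed_base`, `codon_index`, `pos_in_codon`,
#'   `germline_codon`, `observed_codon`. Zero rows when the pair is
#'   identical over compared positions.
#' @export
call_mutations <- function(pair) {
  stopifnot(inherits(pair, "germline_pair"))
  pc <- strsplit(pair$aligned_patient, "", fixed = TRUE)[[1]]
  gc_ <- strsplit(pair$aligned_germline, "", fixed = TRUE)[[1]]
  both <- pc %in% DNA_BASES_STRICT & gc_ %in% DNA_BASES_STRICT
  mut_cols <- which(both & pc != gc_)

  # germline ungapped coordinate of every alignment column (NA at gaps)
  g_nongap <- !(gc_ %in% c(".", "-"))
  g_idx <- ifelse(g_nongap, cumsum(g_nongap), NA_integer_)

  empty <- data.frame(
    patient_id = character(), alignment_pos = integer(),
    germline_base = character(), observed_base = character(),
    codon_index = integer(), pos_in_codon = integer(),
    germline_codon = character(), observed_codon = character(),
    stringsAsFactors = FALSE)
  if (length(mut_cols) == 0L) return(empty)

  fo <- pair$frame_offset
  gu <- paste(gc_[g_nongap], collapse = "")          # ungapped germline
  col_of_g <- which(g_nongap)                        # ungapped index -> column
  n_g <- nchar(gu)

  u <- g_idx[mut_cols]                               # 1-based ungapped pos
  rel <- u - 1L - fo
  codon_index <- ifelse(rel >= 0L, rel %/% 3L, NA_integer_)
  pos_in_codon <- ifelse(rel >= 0L, rel %% 3L, NA_integer_)
  codon_start <- fo + 3L * codon_index + 1L
  complete <- !is.na(codon_index) & (codon_start + 2L) <= n_g
  germline_codon <- rep(NA_character_, length(mut_cols))
  observed_codon <- rep(NA_character_, length(mut_cols))
  if (any(complete)) {
    cs <- codon_start[complete]
    germline_codon[complete] <- substring(gu, cs, cs + 2L)
    obs <- vapply(cs, function(s) {
      cols <- col_of_g[s:(s + 2L)]
      paste(pc[cols], collapse = "")
    }, character(1))
    obs[!grepl("^[ACGT]{3}$", obs)] <- NA_character_
    observed_codon[complete] <- obs
  }
  data.frame(
    patient_id = rep(pair$patient_id, length(mut_cols)),
    alignment_pos = mut_cols - 1L,
    germline_base = gc_[mut_cols],
    observed_base = pc[mut_cols],
    codon_index = codon_index,
    pos_in_codon = pos_in_codon,
    germline_codon = germline_codon,
    observed_codon = observed_codon,
    stringsAsFactors = FALSE)
}

#' Percent nucleotide difference from germline
#'
#' 100 x (number of mutated positions) / (number of compared positions),
#' the quantity behind the standard 2% IGHV mutation-status cutoff.
#'
#' @param pair A `germline_pair`.
#' @return Percent difference (numeric scalar).
#' @export
percent_difference <- function(pair) {
  stopifnot(inherits(pair, "germline_pair"))
  if (pair$compared_length <= 0L) stop("compared_length is zero")
  100 * nrow(call_mutations(pair)) / pair$compared_length
}

#' IGHV mutation status from percent difference
#'
#' Dichotomises percent germline difference at the standard cutoff
#' (default 2%). The boundary belongs to the mutated category:
#' `pct >= cutoff` is `"mutated"` (M-CLL), `pct < cutoff` is
#' `"unmutated"` (U-CLL).
#'
#' @param pct Percent difference (vectorised).
#' @param percent_cutoff Cutoff in percent, default 2.
#' @return Character vector, `"unmutated"` or `"mutated"`.
#' @export
mutation_status <- function(pct, percent_cutoff = 2.0) {
  if (percent_cutoff <= 0 || percent_cutoff >= 100) {
    stop("percent_cutoff must be in (0, 100)")
  }
  if (any(pct < 0, na.rm = TRUE)) stop("percent difference cannot be negative")
  ifelse(pct >= percent_cutoff, "mutated", "unmutated")
}
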