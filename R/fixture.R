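#' Deterministic 12-patient hand-checkable cohort
#'
#' A fixed synthetic cohort whose every mutation was placed by hand so
#' all downstream numbers can be verified by hand. It covers all four
#' composition categories (0 Mut x4, S-only x1, R-only x3, S+R x4), a
#' sequence whose ratio is exactly 1.0 (S=3, Rc=2, Rnc=5, so
#' 5.05/5.05 — boundary, Low group), a mutation to a stop codon
#' (TGG -> TGA, Rnc), two sequences with a single mutation (below the 2%
#' cutoff despite carrying a mutation), and one Low Ratio patient with
#' no exact-count counterpart in the High group (unmatched under exact
#' matching). Reruns are byte-identical: no randomness is involved.
#'
#' The `truth` table carries the intended (hand-derived) labels, so it
#' doubles as an independent oracle for the classifier and pipeline.
#'
#' @return A `simulated_cohort` (see [simulate_cohort()]); `config` is
#'   `NULL`.
#' @export
fixture_small <- function() {
  codons <- c("ATG", "CTA", "GAG", "TGG", "TCA", "GCC", "AAA", "GAT", "TTT",
              "CCC", "CTT", "GGT", "ACT", "GTG", "GAC", "CAG", "CAC", "ATC",
              "AGC", "TAC", "AAC", "GGA", "GCT", "GTT", "CAA", "ACC", "TGC",
              "CGT", "ATT", "GAA")
  germ <- setNames(paste(codons, collapse = ""), "IGHVF1-1*01")

  # edits: codon index (1-based), position in codon (1-3), new base
  edit <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(codon = m[, 1], pos = m[, 2], to = c("A", "C", "G", "T")[m[, 3]])
  }
  b <- c(A = 1, C = 2, G = 3, T = 4)
  # named single edits reused across patients (label given for the record)
  e_s_cta <- c(2, 3, b[["G"]])    # CTA->CTG  L->L  S
  e_s_tca <- c(5, 3, b[["T"]])    # TCA->TCT  S->S  S
  e_s_gcc <- c(6, 3, b[["A"]])    # GCC->GCA  A->A  S
  e_s_ttc <- c(9, 3, b[["C"]])    # TTT->TTC  F->F  S
  e_s_ggc <- c(12, 3, b[["C"]])   # GGT->GGC  G->G  S
  e_s_acc <- c(13, 3, b[["C"]])   # ACT->ACC  T->T  S
  e_rc_aga <- c(7, 2, b[["G"]])   # AAA->AGA  K->R  Rc (all axes agree)
  e_rc_att <- c(11, 1, b[["A"]])  # CTT->ATT  L->I  Rc (all axes agree)
  e_rnc_aag <- c(3, 1, b[["A"]])  # GAG->AAG  E->K  Rnc (volume+chemistry differ)
  e_rnc_stop <- c(4, 3, b[["A"]]) # TGG->TGA  W->*  Rnc, to_stop
  e_rnc_gaa <- c(8, 3, b[["A"]])  # GAT->GAA  D->E  Rnc strict (volume differs)
  e_rnc_tct <- c(9, 2, b[["C"]])  # TTT->TCT  F->S  Rnc
  e_rnc_cgc <- c(10, 2, b[["G"]]) # CCC->CGC  P->R  Rnc

  muts <- list(
    pt01 = NULL, pt02 = NULL, pt03 = NULL, pt04 = NULL,
    pt05 = edit(e_s_cta),                                        # S only, n=1
    pt06 = edit(e_rc_aga),                                       # R only, n=1
    pt07 = edit(e_rc_aga, e_rnc_aag, e_rnc_gaa),                 # R only, n=3
    pt08 = edit(e_s_cta, e_s_tca, e_s_gcc, e_rc_aga, e_rc_att,   # S+R, n=10
                e_rnc_aag, e_rnc_stop, e_rnc_gaa, e_rnc_tct, e_rnc_cgc),
    pt09 = edit(e_s_cta, e_s_tca, e_rnc_aag),                    # S+R, n=3
    pt10 = edit(e_s_cta, e_s_tca, e_s_gcc, e_s_ttc, e_rc_aga),   # S+R, n=5
    pt11 = edit(e_rnc_aag, e_rnc_gaa, e_rnc_tct, e_rnc_cgc),     # R only, n=4
    pt12 = edit(e_s_cta, e_s_tca, e_s_gcc, e_s_ttc, e_s_ggc,     # S+R, n=10
                e_s_acc, e_rc_aga, e_rc_att, e_rnc_aag, e_rnc_gaa))

  apply_edits <- function(ed) {
    s <- germ[[1]]
    if (is.null(ed)) return(s)
    p <- 3L * (ed$codon - 1L) + ed$pos
    for (i in seq_len(nrow(ed))) substr(s, p[i], p[i]) <- ed$to[i]
    s
  }
  pid <- names(muts)
  seqs <- vapply(muts, apply_edits, character(1))

  truth <- data.frame(
    patient_id = pid,
    n_s = c(0, 0, 0, 0, 1, 0, 0, 3, 2, 4, 0, 6),
    n_rc = c(0, 0, 0, 0, 0, 1, 1, 2, 0, 1, 0, 2),
    n_rnc = c(0, 0, 0, 0, 0, 0, 2, 5, 1, 0, 4, 2),
    stringsAsFactors = FALSE)
  truth$n_total <- truth$n_s + truth$n_rc + truth$n_rnc
  truth <- compute_ratio(truth)
  truth$v_call <- names(germ)
  truth$category <- c(rep("0_mut", 4), "s_only", "r_only", "r_only",
                      "s_plus_r", "s_plus_r", "s_plus_r", "r_only", "s_plus_r")

  clinical <- data.frame(
    patient_id = pid,
    ttft_years = c(1.2, 0.8, 2.5, 3.0, 2.0, 1.5, 4.0, 6.5, 5.0, 8.0, 3.5, 10.0),
    event = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE,
              TRUE, FALSE),
    stringsAsFactors = FALSE)

  rearr <- data.frame(
    sequence_id = pid, sequence = unname(seqs),
    sequence_alignment = unname(seqs),
    germline_alignment = rep(germ[[1]], length(pid)),
    v_call = rep(names(germ), length(pid)), stringsAsFactors = FALSE)

  structure(list(germline = germ, rearrangements = rearr, clinical = clinical,
                 truth = truth, config = NULL),
            class = "simulated_cohort")
}
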