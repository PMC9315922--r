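test_that("identical sequences give full compared length and no mutations", {
  s <- strrep("ACGTGT", 50)                 # 300 nt
  pair <- align_pair(s, s, patient_id = "p")
  expect_equal(pair$compared_length, 300L)
  expect_equal(nrow(call_mutations(pair)), 0L)
  expect_equal(percent_difference(pair), 0)
})

test_that("pre-aligned equal-length pairs pass through with mismatches called", {
  g <- strrep("ATGGCA", 20)                 # 120 nt
  p <- g
  substr(p, 4, 4) <- "T"; substr(p, 61, 61) <- "C"; substr(p, 120, 120) <- "T"
  pair <- align_pair(p, g, patient_id = "p")
  sites <- call_mutations(pair)
  expect_equal(sites$alignment_pos, c(3L, 60L, 119L))
  expect_equal(sites$germline_base, c("G", "A", "A"))
  expect_equal(sites$observed_base, c("T", "C", "T"))
  expect_equal(sites$codon_index, c(1L, 20L, 39L))
  expect_equal(sites$pos_in_codon, c(0L, 0L, 2L))
  expect_equal(sites$germline_codon, c("GCA", "ATG", "GCA"))
  expect_equal(sites$observed_codon, c("TCA", "CTG", "GCT"))
})

test_that("N-masked and gapped positions are excluded from comparison", {
  g <- paste(rep("ACGT", 30), collapse = "")  # 120
  p <- g
  substr(p, 10, 10) <- "N"                    # masks a (potential) mismatch
  substr(p, 21, 23) <- "---"                  # 3-nt deletion
  substr(p, 50, 50) <- "A"                    # real mutation (germline C here)
  pair <- align_pair(p, g, patient_id = "p")
  expect_equal(pair$compared_length, 120L - 1L - 3L)
  sites <- call_mutations(pair)
  # only the substituted position, never the indel or the N
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$alignment_pos, 49L)
})

test_that("global alignment of unequal-length inputs recovers substitutions", {
  set.seed(31)
  g <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  p <- g
  substr(p, 90, 90) <- setdiff(c("A", "C", "G", "T"), substr(g, 90, 90))[1]
  p_trunc <- substr(p, 1, 290)               # unequal length -> alignment path
  pair <- align_pair(p_trunc, g, patient_id = "p")
  sites <- call_mutations(pair)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$germline_base, substr(g, 90, 90))
  expect_error(align_pair("ACGT", g), "insufficient overlap")
  expect_error(align_pair("", g), "empty")
})

test_that("percent difference and the 36-mutation maximum are exact", {
  g <- strrep("ACGTGT", 50)
  p <- g
  pos <- seq(3, 300, by = 8)[1:36]
  for (i in pos) {
    substr(p, i, i) <- setdiff(c("A", "C", "G", "T"), substr(g, i, i))[1]
  }
  pair <- align_pair(p, g)
  expect_equal(nrow(call_mutations(pair)), 36L)
  expect_equal(percent_difference(pair), 100 * 36 / 300)

  # 6/300 = exactly 2%; 5 over 290 = 500/290
  p2 <- g
  for (i in pos[1:6]) {
    substr(p2, i, i) <- setdiff(c("A", "C", "G", "T"), substr(g, i, i))[1]
  }
  expect_equal(percent_difference(align_pair(p2, g)), 2.0)
})

test_that("mutation count equals a brute-force oracle on random pairs", {
  set.seed(404)
  for (rep in 1:25) {
    rp <- random_pair(len = 150, p_mut = runif(1, 0, 0.15))
    pair <- align_pair(rp$patient, rp$germline, min_overlap = 1)
    expect_equal(nrow(call_mutations(pair)),
                 count_mismatches_oracle(rp$patient, rp$germline))
  }
})

test_that("percent difference is invariant to joint reverse-complement", {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  set.seed(77)
  for (rep in 1:10) {
    rp <- random_pair(len = 120, p_gap = 0, p_n = 0)
    a <- align_pair(rp$patient, rp$germline, min_overlap = 1)
    b <- align_pair(revcomp(rp$patient), revcomp(rp$germline), min_overlap = 1)
    expect_equal(percent_difference(a), percent_difference(b))
  }
})

test_that("mutation status dichotomises at the 2% boundary, boundary mutated", {
  expect_equal(mutation_status(2.0), "mutated")
  expect_equal(mutation_status(0.0), "unmutated")
  expect_equal(mutation_status(1.9999), "unmutated")
  # monotone in pct
  pct <- sort(runif(50, 0, 5))
  st <- mutation_status(pct)
  expect_false(is.unsorted(match(st, c("unmutated", "mutated"))))
  expect_error(mutation_status(1, percent_cutoff = 0), "percent_cutoff")
})
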