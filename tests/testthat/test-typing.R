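test_that("codon translation follows the standard genetic code", {
  expect_equal(translate_codon(c("ATG", "TAA", "CTG")), c("M", "*", "L"))
  expect_error(translate_codon("ANG"), "unambiguous")
  expect_error(translate_codon("AT"), "unambiguous")
})

test_that("class tables partition the 20 amino acids on each axis", {
  tabs <- aa_class_tables()
  for (axis in names(tabs)) {
    expect_length(tabs[[axis]], 20L)
    expect_setequal(names(tabs[[axis]]), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  }
  expect_setequal(unique(tabs$hydropathy), c("hydrophobic", "neutral", "hydrophilic"))
  expect_length(unique(tabs$volume), 5L)
  expect_length(unique(tabs$chemistry), 7L)
})

test_that("conservativeness calls match hand-derived class comparisons", {
  # L -> I: hydrophobic/large/aliphatic on both sides
  li <- classify_aa_change("L", "I")
  expect_true(li$conservative)
  expect_true(all(li$axis_agreement))
  # D -> K: volume and chemistry differ
  dk <- classify_aa_change("D", "K")
  expect_false(dk$conservative)
  expect_equal(unname(dk$axis_agreement), c(TRUE, FALSE, FALSE))
  # L -> M: only chemistry (aliphatic vs sulfur) differs -> rule-dependent
  expect_false(classify_aa_change("L", "M", rule = "strict")$conservative)
  expect_true(classify_aa_change("L", "M", rule = "majority")$conservative)
  expect_error(classify_aa_change("L", "L"), "not a replacement")
})

test_that("single-site classification handles S, Rnc and stop codons", {
  site <- function(gc, pos, obs) list(germline_codon = gc, pos_in_codon = pos,
                                      observed_base = obs, observed_codon = NA)
  s <- classify_nt_mutation(site("CTG", 2L, "A"))   # CTG -> CTA, both Leu
  expect_equal(s$label, "S")
  ek <- classify_nt_mutation(site("GAG", 0L, "A"))  # GAG(E) -> AAG(K)
  expect_equal(ek$label, "Rnc")
  expect_false(ek$to_stop)
  st <- classify_nt_mutation(site("TGG", 2L, "A"))  # TGG(W) -> TGA(*)
  expect_equal(st$label, "Rnc")
  expect_true(st$to_stop)
  un <- classify_nt_mutation(site("CNG", 1L, "A"))  # ambiguous codon context
  expect_true(is.na(un$label))
})

test_that("S/R split agrees with an independent translate-and-compare oracle on all 549 changes", {
  skip_if_not_installed("seqinr")
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  grid <- expand.grid(codon = sense, pos = 0:2, alt = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  grid <- grid[substr(grid$codon, grid$pos + 1, grid$pos + 1) != grid$alt, ]
  expect_equal(nrow(grid), 549L)

  sites <- data.frame(germline_codon = grid$codon, pos_in_codon = grid$pos,
                      observed_base = grid$alt)
  got <- classify_sites(sites)

  mutant <- grid$codon
  substr(mutant, grid$pos + 1, grid$pos + 1) <- grid$alt
  aa_from <- vapply(grid$codon, function(cd)
    seqinr::translate(seqinr::s2c(cd)), character(1))
  aa_to <- vapply(mutant, function(cd)
    seqinr::translate(seqinr::s2c(cd)), character(1))
  oracle_sr <- ifelse(aa_from == aa_to, "S", "R")

  got_sr <- ifelse(got$label == "S", "S", "R")
  expect_identical(unname(got_sr), unname(oracle_sr))
  # no NA labels among sense-codon changes; stop-gaining are Rnc+to_stop
  expect_false(anyNA(got$label))
  expect_true(all(got$label[aa_to == "*"] == "Rnc"))
  expect_true(all(got$to_stop[aa_to == "*"]))
  expect_false(any(got$to_stop[aa_to != "*"]))
})

test_that("conservativeness is symmetric and majority is a superset of strict", {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pairs <- expand.grid(a = aas, b = aas, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  for (i in seq_len(nrow(pairs))) {
    ab_s <- classify_aa_change(pairs$a[i], pairs$b[i], rule = "strict")
    ba_s <- classify_aa_change(pairs$b[i], pairs$a[i], rule = "strict")
    expect_identical(ab_s$conservative, ba_s$conservative)
    ab_m <- classify_aa_change(pairs$a[i], pairs$b[i], rule = "majority")
    expect_true(ab_m$conservative >= ab_s$conservative)
  }
})

test_that("every classified site gets exactly one label and profiles add up", {
  set.seed(9)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  n <- 200
  codon <- sample(sense, n, replace = TRUE)
  pos <- sample(0:2, n, replace = TRUE)
  cur <- substr(codon, pos + 1, pos + 1)
  alt <- vapply(cur, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  got <- classify_sites(data.frame(germline_codon = codon, pos_in_codon = pos,
                                   observed_base = alt))
  expect_true(all(got$label %in% c("S", "Rc", "Rnc")))
  prof <- profile_sequence(got$label, pct = 1, status = "unmutated")
  expect_equal(prof$n_s + prof$n_rc + prof$n_rnc, prof$n_total)
  expect_equal(prof$n_total + prof$n_unclassified, n)
})

test_that("profile categories follow the counts", {
  expect_equal(profile_sequence(character(0))$category, "0_mut")
  expect_equal(profile_sequence(c("S", "S", "Rnc"))$category, "s_plus_r")
  expect_equal(profile_sequence(c("Rc", "Rnc"))$category, "r_only")
  expect_equal(profile_sequence(c("S"))$category, "s_only")
  expect_equal(profile_sequence(c("S", NA))$n_unclassified, 1L)
})

test_that("observed-codon joint effect differs from isolated effect when a codon is hit twice", {
  # germline CTG (L); two observed changes make the observed codon ATA (I)
  # isolated effect of pos-0 C->A: CTG -> ATG (M) = Rnc (strict)
  # joint effect: CTG -> ATA (L -> I) = Rc
  site <- list(germline_codon = "CTG", pos_in_codon = 0L, observed_base = "A",
               observed_codon = "ATA")
  iso <- classify_nt_mutation(site, effect = "isolated")
  joint <- classify_nt_mutation(site, effect = "observed")
  expect_equal(iso$label, "Rnc")
  expect_equal(joint$label, "Rc")
})
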