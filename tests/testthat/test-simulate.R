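test_that("germline generation is stop-free, framed and reproducible", {
  g <- make_germline(5, 300, seed = 4)
  expect_length(g, 5)
  expect_true(all(nchar(g) == 300))
  for (s in g) {
    codons <- substring(s, seq(1, 298, 3), seq(3, 300, 3))
    expect_false(any(translate_codon(codons) == "*"))
  }
  expect_identical(g, make_germline(5, 300, seed = 4))
  expect_false(identical(g, make_germline(5, 300, seed = 5)))
  expect_error(make_germline(2, 299), "divisible by 3")
})

test_that("mutate_sequence makes exactly n distinct substitutions, no indels", {
  g <- make_germline(1, 300, seed = 6)[[1]]
  m0 <- mutate_sequence(g, 0, seed = 1)
  expect_identical(m0$sequence, g)

  m <- mutate_sequence(g, 36, seed = 2)
  expect_equal(nchar(m$sequence), 300L)
  expect_equal(nrow(m$sites), 36L)
  expect_false(anyDuplicated(m$sites$position) > 0)
  expect_true(all(m$sites$from != m$sites$to))
  # round-trip: mutation calling recovers exactly the true sites
  pair <- align_pair(m$sequence, g)
  called <- call_mutations(pair)
  expect_equal(called$alignment_pos + 1L, m$sites$position)
  expect_equal(called$observed_base, m$sites$to)
  expect_equal(called$germline_base, m$sites$from)
  expect_error(mutate_sequence(g, 301), "exceeds")
})

test_that("transition:transversion substitution weights are respected", {
  g <- make_germline(34, 300, seed = 7)
  sites <- do.call(rbind, lapply(seq_along(g), function(i) {
    mutate_sequence(g[[i]], 300, ts_weight = 2, seed = 100 + i)$sites
  }))
  is_transition <- with(sites, (from == "A" & to == "G") |
                          (from == "G" & to == "A") |
                          (from == "C" & to == "T") | (from == "T" & to == "C"))
  n <- nrow(sites)            # 10,200 draws, expected transition share 0.5
  expect_equal(n, 10200L)
  tol <- 3 * sqrt(0.5 * 0.5 / n)
  expect_lt(abs(mean(is_transition) - 0.5), tol)
})

test_that("hotspot weighting enriches mutations inside WRC/GYW motifs", {
  g <- make_germline(1, 3000, seed = 8)[[1]]
  chars <- strsplit(g, "")[[1]]
  hot <- ighvratio:::.hotspot_positions(chars)
  base_frac <- mean(hot)
  hits <- unlist(lapply(1:30, function(i) {
    mutate_sequence(g, 60, hotspot_multiplier = 5, seed = 300 + i)$sites$position
  }))
  got_frac <- mean(hot[hits])
  # expected enrichment: 5f / (5f + (1-f))
  expect_gt(got_frac, base_frac * 2)
})

test_that("zero-mutation fraction follows its Bernoulli target", {
  cfg <- sim_config(n_patients = 10, seed = 1)
  withr::with_seed(99, {
    b <- draw_mutation_burden(10000, cfg)
  })
  tol <- 3 * sqrt(0.35 * 0.65 / 10000)
  expect_lt(abs(mean(b == 0) - 0.35), tol)
  expect_true(all(b >= 0 & b <= 36))
  # burden pmf is a proper distribution over 1..36
  expect_equal(sum(default_burden_pmf()), 1)
  expect_length(default_burden_pmf(), 36L)
})

test_that("simulated cohorts are reproducible and internally consistent", {
  cfg <- sim_config(n_patients = 150, seed = 17)
  sc <- simulate_cohort(cfg)
  sc2 <- simulate_cohort(cfg)
  expect_identical(sc$rearrangements, sc2$rearrangements)
  expect_identical(sc$clinical, sc2$clinical)
  expect_identical(sc$truth, sc2$truth)

  expect_true(all(sc$clinical$ttft_years > 0))
  expect_true(all(sc$clinical$ttft_years <= cfg$admin_censor_years))
  expect_equal(nchar(sc$rearrangements$sequence),
               rep(300L, 150))
  # truth counts are consistent with the emitted sequences by construction
  i <- which(sc$truth$n_total > 0)[1]
  pair <- align_pair(sc$rearrangements$sequence_alignment[i],
                     sc$rearrangements$germline_alignment[i])
  expect_equal(nrow(call_mutations(pair)), sc$truth$n_total[i])
})

test_that("rejection knob populates both ratio groups at the target share", {
  sc <- simulate_cohort(sim_config(n_patients = 120, target_high_frac = 0.6,
                                   seed = 23))
  tab <- table(sc$truth$ratio_group)
  expect_gt(tab[["high"]], 0)
  expect_gt(tab[["low"]], 0)
  # zero-mutation patients never get a group
  expect_true(all(is.na(sc$truth$ratio_group[sc$truth$n_total == 0])))
})

test_that("simulated files round-trip through the readers", {
  sc <- simulate_cohort(sim_config(n_patients = 40, seed = 29))
  d <- tempfile()
  paths <- write_simulated_cohort(sc, d)
  expect_true(all(file.exists(paths)))
  germ <- read_fasta(paths[["germline"]])
  expect_equal(sort(germ$id), sort(names(sc$germline)))
  rear <- read_airr_rearrangements(paths[["rearrangements"]])
  expect_true(all(rear$prealigned))
  clin <- read_clinical(paths[["clinical"]])
  expect_equal(clin$ttft_years, sc$clinical$ttft_years, tolerance = 0)
})
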