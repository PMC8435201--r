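# Bait-design rules: cleaning, tiling, hit filtering, Tm model and the
# specificity filter, plus whole-pipeline determinism.

test_that("N-run replacement respects the run-length threshold and pads short input", {
  expect_identical(clean_sequence("ACGNNACG", pad_to = 8), "ACGTTACG")
  run11 <- paste0("ACG", strrep("N", 11), "ACG")
  expect_identical(clean_sequence(run11, pad_to = 17), run11)
  run10 <- paste0("ACG", strrep("N", 10), "ACG")
  expect_identical(clean_sequence(run10, pad_to = 16),
                   paste0("ACG", strrep("T", 10), "ACG"))
  # soft-masked runs keep their case
  expect_identical(clean_sequence("acgnnacg", pad_to = 8), "acgttacg")
  # padding: 100 bp in, 120 bp out ending in 20 T
  out <- clean_sequence(strrep("A", 100))
  expect_identical(nchar(out), 120L)
  expect_identical(substring(out, 101), strrep("T", 20))
  # idempotence
  x <- paste0("acg", strrep("N", 4), "GGG", strrep("n", 12), strrep("A", 30))
  expect_identical(clean_sequence(clean_sequence(x, pad_to = 60), pad_to = 60),
                   clean_sequence(x, pad_to = 60))
  expect_error(clean_sequence(""), class = "tt_value_error")
})

test_that("tiling enumerates starts at the configured spacing", {
  b1 <- tile_baits(strrep("A", 120))
  expect_identical(nrow(b1), 1L)
  expect_identical(b1$start, 0L)

  b3 <- tile_baits(strrep("A", 220))
  expect_identical(b3$start, c(0L, 50L, 100L))
  expect_identical(nchar(b3$sequence), rep(120L, 3))

  for (L in c(120, 169, 170, 220, 333, 500)) {
    b <- tile_baits(strrep("C", L))
    expect_identical(nrow(b), as.integer(floor((L - 120) / 50) + 1))
    expect_true(all(diff(b$start) == 50L))
    expect_true(all(b$start + b$length <= L))
  }
  expect_error(tile_baits(strrep("A", 119)), class = "tt_value_error")
})

test_that("tiling flags ambiguous and heavily masked candidates", {
  withN <- paste0(strrep("A", 50), strrep("N", 11), strrep("A", 59))
  expect_identical(tile_baits(withN)$status, "rejected:ambiguous")
  masked <- paste0(strrep("A", 80), strrep("a", 40))
  b <- tile_baits(masked)
  expect_identical(b$status, "rejected:masked")
  expect_equal(b$masked_fraction, 40 / 120)
  okmask <- paste0(strrep("A", 95), strrep("a", 25))
  expect_identical(tile_baits(okmask)$status, "candidate")
})

test_that("hit filtering uses strict bounds and matches a predicate-scan oracle", {
  hits <- data.frame(bait_id = "b", target_id = "t",
                     length = c(46, 45, 120, 44, 46),
                     identity = c(76, 99, 75, 80, 75.01))
  kept <- filter_hits(hits)
  expect_identical(nrow(kept), 2L)           # rows 1 and 5 only
  expect_identical(kept$length, c(46, 46))

  set.seed(55)
  rnd <- data.frame(bait_id = "b", target_id = "t",
                    length = sample(30:130, 300, TRUE),
                    identity = runif(300, 60, 100))
  oracle <- rnd[vapply(seq_len(300), function(i)
    rnd$length[i] > 45 && rnd$identity[i] > 75, TRUE), ]
  expect_identical(filter_hits(rnd), oracle)
})

test_that("the Tm model is deterministic and monotone in GC and identity", {
  base <- estimate_tm(120, 100, 50)
  expect_equal(base, 81.5 + 16.6 * log10(0.9) + 0.41 * 50 - 5)  # snapshot
  expect_gt(estimate_tm(120, 100, 60), base)
  expect_lt(estimate_tm(120, 95, 50), base)
  expect_gt(estimate_tm(120, 100, 50), estimate_tm(60, 100, 50))
  expect_error(estimate_tm(0, 100, 50), class = "tt_value_error")
})

test_that("the specificity filter applies the Tm-bin count limits inclusively", {
  cfg <- bait_config()
  # exactly at both limits: 10 mid-bin + 2 high-bin hits -> retained
  tm <- c(rep(63, 10), rep(66, 2))
  expect_identical(specificity_filter("b", tm, cfg)$status, "retained")
  expect_identical(specificity_filter("b", rep(63, 11), cfg)$status,
                   "rejected:mid-bin")
  expect_identical(specificity_filter("b", rep(70, 3), cfg)$status,
                   "rejected:high-bin")
  # bin edges: 62.5 and 65 are mid-bin, just above 65 is high-bin
  expect_identical(specificity_filter("b", c(rep(62.5, 6), rep(65, 5)),
                                      cfg)$status, "rejected:mid-bin")
  expect_identical(specificity_filter("b", numeric(0), cfg)$status, "retained")
  # pluggable flanking predicate
  cfg$flanking_predicate <- function(id, tm) FALSE
  expect_identical(specificity_filter("b", numeric(0), cfg)$status,
                   "rejected:flanking")
})

test_that("the pipeline conserves candidates and is byte-identical across runs", {
  fx <- make_bait_fixture(tempfile("baitsA"), seed = 3)
  dec <- design_baits(fx$fasta, fx$hits)
  expect_true(all(dec$status %in%
    c("retained", "rejected:ambiguous", "rejected:masked",
      "rejected:mid-bin", "rejected:high-bin", "rejected:flanking")))
  expect_identical(sum(dec$status == "retained") +
                     sum(startsWith(dec$status, "rejected:")), nrow(dec))

  # same seed -> byte-identical fixture files and decision tables
  fx2 <- make_bait_fixture(tempfile("baitsB"), seed = 3)
  expect_identical(readLines(fx$fasta), readLines(fx2$fasta))
  expect_identical(readLines(fx$hits), readLines(fx2$hits))
  dec2 <- design_baits(fx2$fasta, fx2$hits)
  expect_identical(dec$sequence, dec2$sequence)
  expect_identical(dec, dec2[, names(dec)])

  fx3 <- make_bait_fixture(tempfile("baitsC"), seed = 4)
  expect_false(identical(readLines(fx$fasta), readLines(fx3$fasta)))
})

test_that("fixture decisions match the hand-enumerated expectation table", {
  fx <- make_bait_fixture(tempfile("baits"), seed = 1)
  dec <- design_baits(fx$fasta, fx$hits)
  expect_identical(dec$bait_id, fx$expected$bait_id)
  expect_identical(dec$status, fx$expected$status)
})
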