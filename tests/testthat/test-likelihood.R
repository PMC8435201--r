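# The fixed-topology likelihood engine: gamma discretisation, empirical
# frequencies, transition probabilities, pruning, and branch-length
# optimisation, each checked against an independent oracle.

test_that("discrete gamma categories have unit mean and match quadrature", {
  g1 <- discrete_gamma_rates(2.7, 1)
  expect_identical(g1$rates, 1)

  g <- discrete_gamma_rates(1e6, 4)          # vanishing heterogeneity
  expect_true(all(abs(g$rates - 1) < 1e-2))

  # adaptive-quadrature oracle for the truncated-gamma category means
  alpha <- 0.5; n <- 4
  cuts <- qgamma(seq(0, 1, length.out = n + 1), alpha, alpha)
  oracle <- vapply(seq_len(n), function(i) {
    stats::integrate(function(x) x * dgamma(x, alpha, alpha),
                     cuts[i], cuts[i + 1], rel.tol = 1e-10)$value * n
  }, 0)
  got <- discrete_gamma_rates(alpha, n)
  expect_lt(max(abs(got$rates - oracle)), 1e-6)
  expect_lt(abs(sum(got$rates * got$weights) - 1), 1e-10)
  expect_true(all(got$rates > 0))

  expect_error(discrete_gamma_rates(0, 4), class = "tt_value_error")
  expect_error(discrete_gamma_rates(-1, 4), class = "tt_value_error")
})

test_that("empirical frequencies match a counting oracle with pseudo-mass for zeros", {
  set.seed(11)
  chars <- sample(strsplit("ARNDCQEGHILKMFPSTWY", "")[[1]], 200, replace = TRUE)
  aln <- alignment(c(A = paste(chars[1:100], collapse = ""),
                     B = paste(chars[101:200], collapse = "")), "aa")
  f <- empirical_frequencies(aln)
  counts <- table(factor(chars, levels = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]))
  # V never drawn: gets pseudo-frequency 1/(2*200), all renormalised
  expected <- as.numeric(counts) / 200
  expected[expected == 0] <- 1 / 400
  expected <- expected / sum(expected)
  expect_lt(max(abs(f - expected)), 1e-12)
  expect_lt(abs(sum(f) - 1), 1e-12)
  expect_true(all(f > 0))

  uni <- alignment(c(A = "ARNDCQEGHILKMFPSTWYV"), "aa")
  expect_true(all(abs(empirical_frequencies(uni) - 0.05) < 1e-12))
  expect_error(empirical_frequencies(alignment(c(A = "???"), "aa")),
               class = "tt_value_error")
})

test_that("the rate matrix is normalised to one expected substitution per site", {
  m <- substitution_model("LG", alpha = 0.5)
  expect_lt(max(abs(rowSums(m$Q))), 1e-12)
  expect_lt(abs(sum(m$frequencies * -diag(m$Q)) - 1), 1e-12)
  expect_lt(abs(sum(m$frequencies) - 1), 1e-12)
})

test_that("transition probabilities satisfy identity, stationarity and the Poisson closed form", {
  m <- substitution_model("WAG", alpha = 1, n_rate_categories = 1)
  expect_identical(transition_probabilities(m, 0), diag(20))
  P <- transition_probabilities(m, 1000)
  expect_lt(max(abs(sweep(P, 2, m$frequencies))), 1e-6)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  expect_true(all(P >= 0))

  # equal-rates closed form: P_ii = 1/k + (1 - 1/k) exp(-k t / (k-1))
  pois <- dna_model()
  for (t in c(0.01, 0.1, 1)) {
    P <- transition_probabilities(pois, t)
    pii <- 1 / 4 + (3 / 4) * exp(-4 * t / 3)
    pij <- 1 / 4 - (1 / 4) * exp(-4 * t / 3)
    expect_lt(max(abs(diag(P) - pii)), 1e-10)
    expect_lt(max(abs(P[row(P) != col(P)] - pij)), 1e-10)
  }
  expect_error(transition_probabilities(pois, -0.1), class = "tt_value_error")
  expect_error(transition_probabilities(pois, 0.1, 0), class = "tt_value_error")
})

test_that("degenerate trees and impossible sites are handled exactly", {
  m <- dna_model(freq = c(0.1, 0.2, 0.3, 0.4))
  # single-leaf tree: site lnL is ln pi of the observed state
  tr1 <- read_newick("(A:0.5);")
  aln1 <- alignment(c(A = "ACN"), "dna")
  expect_equal(site_log_likelihoods(aln1, tr1, m),
               c(log(0.1), log(0.2), 0))
  # conflicting states across zero-length branches: probability exactly 0
  tr0 <- read_newick("(A:0,B:0);")
  aln0 <- alignment(c(A = "A", B = "C"), "dna")
  expect_identical(site_log_likelihoods(aln0, tr0, m), -Inf)
  # leaf missing from the alignment
  expect_error(site_log_likelihoods(aln0, read_newick("(A:1,Z:1);"), m),
               class = "tt_value_error")
})

test_that("pruning equals exhaustive enumeration on a 4-taxon mixture model", {
  m <- substitution_model("Poisson", alphabet = "generic",
                          symbols = c("A", "B"),
                          frequencies = c(0.3, 0.7),
                          alpha = 0.6, n_rate_categories = 3)
  tr <- read_newick("((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  aln <- alignment(c(A = "A", B = "A", C = "B", D = "B"), "generic",
                   symbols = c("A", "B"))
  expect_lt(abs(site_log_likelihoods(aln, tr, m) -
                brute_site_lnl(aln, tr, m)), 1e-12)
})

test_that("total lnL is additive and equals the site-wise sum", {
  m <- dna_model(alpha = 0.8, ncat = 4)
  tr <- read_newick("((A:0.2,B:0.1):0.05,(C:0.3,D:0.15):0.1);")
  aln <- simulate_alignment(tr, m, 500, seed = 21)
  s <- site_log_likelihoods(aln, tr, m)
  expect_lt(abs(tree_log_likelihood(aln, tr, m) - sum(s)), 1e-8)

  doubled <- alignment(cbind(unclass(aln), unclass(aln)), "dna")
  expect_equal(tree_log_likelihood(doubled, tr, m),
               2 * tree_log_likelihood(aln, tr, m), tolerance = 1e-12)

  empty <- alignment(matrix("A", 4, 0,
                            dimnames = list(c("A", "B", "C", "D"), NULL)),
                     "dna")
  expect_identical(tree_log_likelihood(empty, tr, m), 0)
})

test_that("pruning matches enumeration across all quartet topologies, alphabets and random lengths", {
  set.seed(42)
  for (mod in list(binary_model(), dna_model())) {
    syms <- mod$alphabet$states
    for (tr in quartet_trees()) {
      for (rep in 1:10) {
        t2 <- tr
        t2$edge.length <- runif(nrow(tr$edge), 0.02, 1.5)
        aln <- simulate_alignment(t2, mod, 6,
                                  seed = sample.int(1e6, 1))
        d <- abs(site_log_likelihoods(aln, t2, mod) -
                 brute_site_lnl(aln, t2, mod))
        expect_lt(max(d), 1e-10)
      }
    }
  }
})

test_that("site likelihoods are invariant under re-rooting (pulley principle)", {
  m <- substitution_model("LG", alpha = 0.7)
  tr <- read_newick("((A:0.3,B:0.1):0.07,(C:0.25,D:0.05):0.12,E:0.4);")
  aln <- simulate_alignment(tr, m, 40, seed = 8)
  base <- site_log_likelihoods(aln, tr, m)
  for (og in c("A", "B", "C", "D", "E")) {
    rr <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_lt(max(abs(site_log_likelihoods(aln, rr, m) - base)), 1e-10)
  }
})

test_that("branch-length optimisation recovers a known length and never decreases lnL", {
  m <- dna_model()
  true <- read_newick("(A:0.1,B:0.1);")  # identifiable path length 0.2
  aln <- simulate_alignment(true, m, 5000, seed = 31)
  fit <- optimize_branch_lengths(aln, true, m)
  expect_lt(abs(sum(fit$edge.length) - 0.2) / 0.2, 0.10)
  expect_gte(attr(fit, "log_likelihood"), tree_log_likelihood(aln, true, m))

  # fixed point: an already-optimal tree moves (in lnL) by less than tol
  fit2 <- optimize_branch_lengths(aln, fit, m, tol = 1e-6)
  expect_lt(abs(attr(fit2, "log_likelihood") - attr(fit, "log_likelihood")),
            1e-4)
})

test_that("optimisation reaches the same optimum from perturbed starting lengths", {
  m <- dna_model()
  tr <- read_newick("((A:0.2,B:0.2):0.1,(C:0.2,D:0.2):0.1);")
  aln <- simulate_alignment(tr, m, 800, seed = 13)
  from_truth <- optimize_branch_lengths(aln, tr, m)
  pert <- tr; pert$edge.length <- tr$edge.length * 4
  from_pert <- optimize_branch_lengths(aln, pert, m)
  expect_lt(abs(attr(from_pert, "log_likelihood") -
                attr(from_truth, "log_likelihood")), 1e-4)
})

test_that("optimisation errors on a non-finite starting likelihood", {
  m <- dna_model()
  tr <- read_newick("(A:0,B:0);")
  aln <- alignment(c(A = "A", B = "C"), "dna")
  expect_error(
    optimize_branch_lengths(aln, tr, m, min_branch = 0),
    class = "tt_optimization_error")
})

test_that("simulation followed by inference recovers alpha and branch lengths", {
  m <- dna_model(alpha = 0.5, ncat = 4)
  tr <- read_newick("((A:0.3,B:0.2):0.15,(C:0.25,D:0.35):0.1);")
  aln <- simulate_alignment(tr, m, 10000, seed = 71)
  fit <- estimate_gamma_shape(aln, tr, dna_model(alpha = 2, ncat = 4))
  expect_lt(abs(fit$alpha - 0.5) / 0.5, 0.15)
  po <- ape::reorder.phylo(tr, "postorder")
  rel <- abs(fit$tree$edge.length - po$edge.length) / po$edge.length
  expect_lt(max(rel), 0.15)
})
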