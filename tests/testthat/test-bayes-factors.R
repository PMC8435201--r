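# Harmonic-mean marginal likelihoods, Bayes factors and evidence bands.

test_that("trace reading applies burn-in and thinning bookkeeping", {
  f <- tempfile()
  write.table(data.frame(cycle = 1:10, loglik = -(1:10)), f,
              sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- read_trace(f, "loglik", burn_in = 3, thin = 1)
  expect_length(tr$lnl, 7)
  expect_identical(tr$cycles, 4:10)

  id <- read_trace(f, "loglik")
  expect_identical(id$lnl, -(1:10) + 0)

  # the published sampling regime: 14,000 cycles, 3,000 burn-in, thin 10
  f2 <- tempfile()
  write.table(data.frame(loglik = rnorm(14000, -375000, 10)), f2,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_length(read_trace(f2, "loglik", burn_in = 3000, thin = 10)$lnl, 1100)

  expect_error(read_trace(f, "nope"), class = "tt_format_error")
  expect_error(read_trace(f, "loglik", burn_in = 10), class = "tt_value_error")
})

test_that("pooling concatenates chains with provenance", {
  t1 <- mcmc_trace(c(-1, -2), chain_id = "c1")
  t2 <- mcmc_trace(c(-3, -4, -5), chain_id = "c2")
  pooled <- pool_chains(list(t1, t2))
  expect_length(pooled, 5)
  expect_identical(as.numeric(pooled), c(-1, -2, -3, -4, -5))
  expect_identical(attr(pooled, "provenance")$chain,
                   c("c1", "c1", "c2", "c2", "c2"))
  # order-insensitive multiset equality
  expect_identical(sort(as.numeric(pool_chains(list(t2, t1)))),
                   sort(as.numeric(pooled)))
  expect_identical(as.numeric(pool_chains(t1)), t1$lnl)
  expect_error(pool_chains(list()), class = "tt_value_error")
})

test_that("log harmonic mean is exact on closed-form cases and stable over huge ranges", {
  expect_identical(log_harmonic_mean(rep(-7.25, 10)), -7.25)
  expect_equal(log_harmonic_mean(c(0, -log(2))), -log(1.5), tolerance = 1e-14)

  # samples spanning 1e4 log units: compare against min-shifted arithmetic
  set.seed(2)
  x <- runif(200, -12000, -2000)
  shifted <- min(x) - log(mean(exp(-(x - min(x)))))
  expect_lt(abs(log_harmonic_mean(x) - shifted), 1e-10)
  expect_true(is.finite(log_harmonic_mean(x)))

  expect_error(log_harmonic_mean(numeric(0)), class = "tt_value_error")
  expect_error(log_harmonic_mean(c(-1, Inf)), class = "tt_value_error")
})

test_that("harmonic mean of likelihoods never exceeds max and obeys Jensen", {
  set.seed(4)
  x <- rnorm(500, -1000, 5)
  hm <- log_harmonic_mean(x)
  expect_lte(hm, max(x))
  expect_lt(hm, mean(x))                      # strict unless constant
  expect_identical(log_harmonic_mean(rep(-3, 5)), -3)
  # permutation invariance of the full-sample estimator
  expect_equal(log_harmonic_mean(sample(x)), hm, tolerance = 1e-12)
})

test_that("moving harmonic mean windows grow as ceiling(fraction * cycle)", {
  set.seed(9)
  x <- rnorm(10, -100, 1)
  est <- moving_harmonic_mean(x, window_fraction = 0.33)
  expect_identical(est$series$window, c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L))
  # brute-force windowing oracle
  brute <- vapply(1:10, function(i) {
    w <- max(1, ceiling(0.33 * i))
    log_harmonic_mean(x[(i - w + 1):i])
  }, 0)
  expect_equal(est$series$estimate, brute, tolerance = 1e-14)
  expect_identical(est$log_marginal, brute[10])

  cst <- moving_harmonic_mean(rep(-5, 8))
  expect_true(all(cst$series$estimate == -5))

  # fraction 1: cumulative harmonic mean of the first i samples
  cum <- moving_harmonic_mean(x, window_fraction = 1)
  oracle <- vapply(1:10, function(i) log_harmonic_mean(x[1:i]), 0)
  expect_equal(cum$series$estimate, oracle, tolerance = 1e-14)

  expect_error(moving_harmonic_mean(x, window_fraction = 0),
               class = "tt_value_error")
  expect_error(moving_harmonic_mean(numeric(0)), class = "tt_value_error")
})

test_that("moving estimator agrees with brute force on random AR(1) traces", {
  for (i in 1:100) {
    tr <- simulate_trace(sample(5:40, 1), mean = -500, sd = 3,
                         rho = runif(1, 0, 0.9),
                         seed = derive_seed(314, paste0("mv", i)))
    frac <- runif(1, 0.1, 1)
    est <- moving_harmonic_mean(tr, window_fraction = frac)
    n <- length(tr$lnl)
    brute <- vapply(seq_len(n), function(j) {
      w <- max(1, ceiling(frac * j))
      log_harmonic_mean(tr$lnl[(j - w + 1):j])
    }, 0)
    expect_equal(est$series$estimate, brute, tolerance = 1e-12)
  }
})

test_that("Bayes factors follow the log-of-absolute-difference rule with sign", {
  expect_equal(bayes_factor(exp(2), 0)$bf, 4)
  expect_equal(bayes_factor(0, exp(2))$bf, -4)
  expect_equal(bayes_factor(exp(5.24), 0)$bf, 10.48)
  expect_identical(bayes_factor(exp(2), 0)$direction, "favors T1")
  expect_identical(bayes_factor(0, exp(2))$direction, "favors T0")
  # antisymmetry under argument swap
  for (pair in list(c(-100, -104), c(-3.5, -2), c(0.5, 9))) {
    expect_equal(bayes_factor(pair[1], pair[2])$bf,
                 -bayes_factor(pair[2], pair[1])$bf)
  }
  # the conventional formula is available behind the flag
  expect_equal(bayes_factor(-10, -12, formula = "standard")$bf, 4)
  expect_warning(z <- bayes_factor(-5, -5), "undefined")
  expect_identical(z$bf, 0)
  expect_identical(z$evidence, "none")
  expect_error(bayes_factor(Inf, 0), class = "tt_value_error")
})

test_that("evidence categories follow the published bands", {
  expect_identical(classify_evidence(10.48), "very strong")
  expect_identical(classify_evidence(-8.84), "strong")
  expect_identical(classify_evidence(0), "none")
  expect_identical(classify_evidence(1.99), "none")
  expect_identical(classify_evidence(2), "some")
  expect_identical(classify_evidence(-5.99), "some")
  expect_identical(classify_evidence(6), "strong")
  expect_identical(classify_evidence(-10), "very strong")
  expect_error(classify_evidence(NaN), class = "tt_value_error")
})

test_that("the harmonic-mean estimator is upwardly biased on a known normal model", {
  # conjugate normal model: y_i ~ N(theta, 1), theta ~ N(0, 1).  The log
  # marginal is available in closed form; lnL samples are evaluated at
  # posterior draws of theta.  The harmonic-mean estimate should exceed
  # the truth on average (its documented upward bias).
  n <- 15
  bias <- vapply(1:200, function(r) {
    s <- derive_seed(2024, paste0("hm", r))
    set.seed(s)
    y <- rnorm(n, 0.3, 1)
    v <- 1 / (n + 1); m <- sum(y) / (n + 1)
    # exact identity: log m(y) = lnL(t) + ln prior(t) - ln posterior(t)
    true_marg <- sum(dnorm(y, m, 1, log = TRUE)) +
      dnorm(m, 0, 1, log = TRUE) - dnorm(m, m, sqrt(v), log = TRUE)
    theta <- rnorm(400, m, sqrt(v))
    lnl <- vapply(theta, function(tt) sum(dnorm(y, tt, 1, log = TRUE)), 0)
    log_harmonic_mean(lnl) - true_marg
  }, 0)
  expect_gt(mean(bias), 0)
})
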