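# Synthetic-data generators: forward sequence simulation along a tree,
# per-locus taxon missingness with controlled occupancy, AR(1)
# log-likelihood traces emulating post-burn-in MCMC output, per-site
# log-likelihood matrices with controlled between-tree effect sizes, and
# a hand-enumerated bait-design fixture.  Every generator is a pure
# function of its inputs and seed.

#' Simulate an alignment on a known tree
#'
#' Root states are drawn from the model's equilibrium frequencies; each
#' site is assigned a discrete-gamma rate category and states evolve
#' along every branch via the model's transition probabilities.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param model a [substitution_model].
#' @param n_sites number of sites (>= 1).
#' @param seed RNG seed.
#' @return an [alignment] over the model's alphabet, taxa = tree leaves.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = NULL) {
  if (n_sites < 1L) value_error("n_sites must be >= 1")
  k <- model$k
  ab <- model$alphabet
  with_seed(seed, {
    ncat <- length(model$rates)
    cat_of_site <- sample.int(ncat, n_sites, replace = TRUE,
                              prob = model$weights)
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    edge <- tree$edge
    # parent-before-child order = reversed post-order
    ord <- rev(seq_len(nrow(edge)))
    po <- ape::reorder.phylo(tree, "postorder")
    states <- matrix(NA_integer_, nnode, n_sites)
    root <- po$edge[nrow(po$edge), 1L]
    states[root, ] <- sample.int(k, n_sites, replace = TRUE,
                                 prob = model$frequencies)
    for (j in ord) {
      pa <- po$edge[j, 1L]; ch <- po$edge[j, 2L]; t <- po$edge.length[j]
      for (c in seq_len(ncat)) {
        P <- transition_probabilities(model, t, model$rates[c])
        sel <- which(cat_of_site == c)
        ps <- states[pa, sel]
        for (s in unique(ps)) {
          idx <- sel[ps == s]
          states[ch, idx] <- sample.int(k, length(idx), replace = TRUE,
                                        prob = P[s, ])
        }
      }
    }
    mat <- matrix(ab$states[states[seq_len(ntip), , drop = FALSE]],
                  nrow = ntip, dimnames = list(tree$tip.label, NULL))
    alignment(mat, ab)
  })
}

#' Simulate per-locus taxon missingness masks
#'
#' For each locus an occupancy (number of taxa retained) is drawn
#' uniformly from `occupancy_range`; that many taxa are chosen uniformly
#' at random, the rest are masked to missing.
#'
#' @param loci_lengths integer vector of locus lengths (defines the
#'   number of loci).
#' @param n_taxa total number of taxa.
#' @param occupancy_range `c(min, max)` within `[1, n_taxa]`.
#' @param seed RNG seed.
#' @return list of logical vectors (length `n_taxa`, `TRUE` = retained),
#'   one per locus.
#' @export
simulate_missingness <- function(loci_lengths, n_taxa, occupancy_range,
                                 seed = NULL) {
  lo <- occupancy_range[1]; hi <- occupancy_range[2]
  if (lo < 1 || hi > n_taxa || lo > hi)
    value_error("occupancy range must lie within [1, %d]", n_taxa)
  with_seed(seed, {
    lapply(seq_along(loci_lengths), function(i) {
      occ <- if (lo == hi) lo else sample(seq.int(lo, hi), 1L)
      keep <- rep(FALSE, n_taxa)
      keep[sample.int(n_taxa, occ)] <- TRUE
      keep
    })
  })
}

#' Apply missingness masks to per-locus alignments
#'
#' Convenience wrapper: masks taxa flagged absent in each locus to the
#' fully missing symbol, emulating patchy target-capture recovery.
#'
#' @param loci named list of [alignment] objects over a common taxon set.
#' @param masks output of [simulate_missingness()] (aligned with `loci`).
#' @return list of alignments with masked taxa replaced by `"?"`.
#' @export
apply_missingness <- function(loci, masks) {
  stopifnot(length(loci) == length(masks))
  out <- lapply(seq_along(loci), function(i) {
    a <- loci[[i]]
    m <- unclass(a)
    m[!masks[[i]], ] <- "?"
    alignment(m, attr(a, "alphabet"))
  })
  names(out) <- names(loci)
  out
}

#' Simulate a stationary AR(1) posterior log-likelihood trace
#'
#' `x_i = mean + rho * (x_{i-1} - mean) + eps_i` with
#' `eps ~ Normal(0, sd^2 * (1 - rho^2))` and
#' `x_1 ~ Normal(mean, sd^2)`, so the marginal distribution is
#' `Normal(mean, sd^2)` at every cycle.
#'
#' @param n_cycles trace length (>= 1).
#' @param mean stationary mean of the log-likelihood samples.
#' @param sd stationary (marginal) standard deviation (> 0).
#' @param rho lag-1 autocorrelation in `[0, 1)`.
#' @param seed RNG seed.
#' @param chain_id chain label.
#' @return an [mcmc_trace].
#' @export
simulate_trace <- function(n_cycles, mean, sd, rho = 0, seed = NULL,
                           chain_id = "sim") {
  if (n_cycles < 1L) value_error("n_cycles must be >= 1")
  if (sd <= 0) value_error("sd must be > 0")
  if (rho < 0 || rho >= 1) value_error("rho must be in [0, 1)")
  with_seed(seed, {
    x <- numeric(n_cycles)
    x[1] <- stats::rnorm(1, mean, sd)
    if (n_cycles > 1L) {
      eps <- stats::rnorm(n_cycles - 1L, 0, sd * sqrt(1 - rho^2))
      for (i in 2:n_cycles) x[i] <- mean + rho * (x[i - 1] - mean) + eps[i - 1]
    }
    mcmc_trace(x, chain_id = chain_id)
  })
}

#' Simulate a per-site log-likelihood matrix with controlled effects
#'
#' Site lnL of tree j at site i is `base_i + offset_j + noise_ij` with
#' `base_i ~ Normal(-3, 1)` truncated at 0 and
#' `noise ~ Normal(0, site_sd^2)`; all values are clipped at 0 to keep
#' the discrete-data invariant lnL <= 0 (a modelling convenience, not a
#' claim about real data).
#'
#' @param n_trees,n_sites matrix dimensions.
#' @param tree_offsets per-tree mean lnL offset (length `n_trees`).
#' @param site_sd site-level noise standard deviation (> 0).
#' @param seed RNG seed.
#' @return a [site_lnl_matrix()].
#' @export
simulate_site_lnl <- function(n_trees, n_sites, tree_offsets = rep(0, n_trees),
                              site_sd = 0.1, seed = NULL) {
  if (length(tree_offsets) != n_trees)
    value_error("tree_offsets must have length n_trees")
  if (site_sd <= 0) value_error("site_sd must be > 0")
  if (n_trees < 1L || n_sites < 1L) value_error("dimensions must be >= 1")
  with_seed(seed, {
    base <- pmin(stats::rnorm(n_sites, -3, 1), 0)
    noise <- matrix(stats::rnorm(n_trees * n_sites, 0, site_sd),
                    n_trees, n_sites)
    vals <- pmin(sweep(noise, 2, base, `+`) + tree_offsets, 0)
    site_lnl_matrix(vals, paste0("T", seq_len(n_trees) - 1L))
  })
}

#' Deterministic bait-design fixture with hand-enumerated expectations
#'
#' Writes a small soft-masked FASTA, a hit table and the expected
#' decision for every candidate, exercising each bait-design rule at its
#' boundary: a 10-N run (replaced) vs an 11-N run (kept, candidate
#' rejected as ambiguous), a 100-bp fragment (T-padded), a clean 220-bp
#' sequence (exactly 3 tiles) whose three candidates test the strict
#' 45-bp/75%-identity hit bounds and the 10-hit mid-bin / 2-hit high-bin
#' limits, and a heavily soft-masked sequence.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed for the random base fill (outputs are
#'   byte-identical for the same seed).
#' @return list with paths `fasta`, `hits`, `expected` and the
#'   `expected` data frame itself.
#' @export
make_bait_fixture <- function(dir = tempdir(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rand_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")
  with_seed(derive_seed(seed, "bait-fixture"), {
    s_nrun10 <- paste0(rand_bases(50), strrep("N", 10), rand_bases(60))
    s_nrun11 <- paste0(rand_bases(50), strrep("N", 11), rand_bases(59))
    s_short100 <- rand_bases(100)
    s_clean220 <- rand_bases(220)
    s_masked <- paste0(rand_bases(40), tolower(rand_bases(40)), rand_bases(40))
    seqs <- c(s_nrun10 = s_nrun10, s_nrun11 = s_nrun11,
              s_short100 = s_short100, s_clean220 = s_clean220,
              s_masked = s_masked)
  })
  fasta <- file.path(dir, "bait_fixture_sequences.fasta")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), fasta)

  hit <- function(bait, n, len, id, tm)
    data.frame(bait_id = bait, target_id = sprintf("g%d", seq_len(n)),
               length = len, identity = id, tm = tm,
               stringsAsFactors = FALSE)
  hits <- rbind(
    # b1 of the 220-bp sequence: exactly 10 valid mid-bin hits and 2
    # valid high-bin hits (both at their limits), plus two boundary hits
    # (length 45 / identity 75) that the strict filter must drop -- if
    # either survived, the mid-bin count would exceed 10.
    hit("s_clean220_b1", 10, 46, 76, 63.0),
    hit("s_clean220_b1", 2, 50, 80, 66.0),
    hit("s_clean220_b1", 1, 45, 99, 63.0),
    hit("s_clean220_b1", 1, 99, 75, 63.0),
    # b2: 11 mid-bin hits -> one over the limit.
    hit("s_clean220_b2", 11, 50, 80, 63.5),
    # b3: 3 high-bin hits -> one over the limit.
    hit("s_clean220_b3", 3, 50, 80, 70.0))
  hits_path <- file.path(dir, "bait_fixture_hits.tsv")
  utils::write.table(hits, hits_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # hand enumeration: 220 bp tiles at starts 0/50/100 only (150+120>220)
  expected <- data.frame(
    bait_id = c("s_nrun10_b1", "s_nrun11_b1", "s_short100_b1",
                "s_clean220_b1", "s_clean220_b2", "s_clean220_b3",
                "s_masked_b1"),
    status = c("retained", "rejected:ambiguous", "retained",
               "retained", "rejected:mid-bin", "rejected:high-bin",
               "rejected:masked"),
    stringsAsFactors = FALSE)
  expected_path <- file.path(dir, "bait_fixture_expected.tsv")
  utils::write.table(expected, expected_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fasta, hits = hits_path, expected_path = expected_path,
       expected = expected)
}
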