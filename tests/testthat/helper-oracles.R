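# Shared fixtures and independent oracles for the test suite.

# Brute-force tree likelihood: exhaustive sum over all internal-state
# assignments of products of transition probabilities.  Independent of
# the pruning code path (no conditional-likelihood recursion).
brute_site_lnl <- function(aln, tree, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  k <- model$k
  ab <- attr(aln, "alphabet")
  states <- matrix(match(unclass(aln)[tr$tip.label, , drop = FALSE], ab$states),
                   nrow = ntip)
  nnode <- ntip + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  internals <- setdiff(seq_len(nnode), seq_len(ntip))
  ncat <- length(model$rates)
  vapply(seq_len(ncol(states)), function(s) {
    per_cat <- vapply(seq_len(ncat), function(c) {
      Ps <- lapply(seq_len(nrow(tr$edge)), function(j)
        transition_probabilities(model, tr$edge.length[j], model$rates[c]))
      grid <- expand.grid(rep(list(seq_len(k)), length(internals)))
      tot <- 0
      for (g in seq_len(nrow(grid))) {
        asgn <- integer(nnode)
        asgn[internals] <- as.integer(grid[g, ])
        p <- model$frequencies[[asgn[root]]]
        for (j in seq_len(nrow(tr$edge))) {
          pa <- tr$edge[j, 1]; ch <- tr$edge[j, 2]
          if (ch <= ntip) {
            st <- states[ch, s]
            p <- p * if (is.na(st)) 1 else Ps[[j]][asgn[pa], st]
          } else {
            p <- p * Ps[[j]][asgn[pa], asgn[ch]]
          }
        }
        tot <- tot + p
      }
      tot
    }, 0)
    log(sum(model$weights * per_cat))
  }, 0)
}

# The three distinct unrooted 4-taxon topologies on A,B,C,D.
quartet_trees <- function(lengths = "0.1") {
  l <- lengths
  list(
    AB_CD = read_newick(sprintf("((A:%s,B:%s):%s,(C:%s,D:%s):%s);", l, l, l, l, l, l)),
    AC_BD = read_newick(sprintf("((A:%s,C:%s):%s,(B:%s,D:%s):%s);", l, l, l, l, l, l)),
    AD_BC = read_newick(sprintf("((A:%s,D:%s):%s,(B:%s,C:%s):%s);", l, l, l, l, l, l)))
}

# Small models used across tests.
binary_model <- function(alpha = 1, ncat = 1, freq = NULL)
  substitution_model("Poisson", alphabet = "generic", symbols = c("A", "B"),
                     frequencies = freq, alpha = alpha, n_rate_categories = ncat)

dna_model <- function(alpha = 1, ncat = 1, freq = NULL)
  substitution_model("Poisson", alphabet = "dna", frequencies = freq,
                     alpha = alpha, n_rate_categories = ncat)

# Tiny amino-acid alignment builder.
aa_aln <- function(...) alignment(c(...), alphabet = "aa")

# Table of tree log-likelihoods from the published four-tree comparison,
# used by the arithmetic reproduction tests.
published_lnls <- c(T0 = -375741.33, T1 = -375740.41,
                    T2 = -375844.52, T3 = -375944.68)

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%.6g - %.6g| <= %g", actual, expected, tol))
}
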