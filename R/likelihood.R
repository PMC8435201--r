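# Fixed-topology likelihood engine.
#
# Per-site log-likelihoods by Felsenstein pruning (post-order conditional
# likelihoods), averaged over discrete-gamma rate categories and summed
# against the equilibrium frequencies at an arbitrary internal root; by
# time reversibility the result is invariant to the root placement.
# Columns are compressed to unique site patterns before pruning and
# per-node scaling keeps conditional likelihoods in floating range, so
# zero-probability sites come back as -Inf rather than underflow noise.

#' @keywords internal
col_max <- function(x) do.call(pmax, lapply(seq_len(nrow(x)), function(i) x[i, ]))

# Precompute everything pruning needs: post-order edge list, tip state
# encodings, unique site patterns with counts.
#' @keywords internal
lik_engine <- function(aln, tree, model) {
  validate_tree_against_alignment(tree, aln)
  if (!identical(attr(aln, "alphabet")$states, model$alphabet$states))
    value_error("model alphabet does not match alignment alphabet")
  ntip <- length(tree$tip.label)
  tr <- if (ntip > 1L) ape::reorder.phylo(tree, "postorder") else tree
  ab <- attr(aln, "alphabet")
  k <- model$k
  sub <- unclass(aln)[tree$tip.label, , drop = FALSE]
  states <- matrix(match(sub, ab$states), nrow = ntip)  # NA = ambiguous
  n_sites <- ncol(states)
  if (n_sites == 0L) {
    return(list(tree = tr, ntip = ntip, k = k, n_sites = 0L,
                pat_index = integer(0), pat_counts = integer(0), tipP = list()))
  }
  key <- apply(states, 2, paste, collapse = ",")
  upat <- !duplicated(key)
  pat_index <- match(key, key[upat])
  pstates <- states[, upat, drop = FALSE]
  npat <- ncol(pstates)
  tipP <- lapply(seq_len(ntip), function(i) {
    p <- matrix(0, k, npat)
    s <- pstates[i, ]
    amb <- is.na(s)
    p[, amb] <- 1
    if (any(!amb)) p[cbind(s[!amb], which(!amb))] <- 1
    p
  })
  list(tree = tr, ntip = ntip, k = k, n_sites = n_sites,
       pat_index = pat_index, pat_counts = tabulate(pat_index, npat),
       npat = npat, tipP = tipP)
}

# Post-order conditional likelihoods for one rate category.  Returns the
# per-pattern log-likelihood vector.
#' @keywords internal
prune_category <- function(en, lengths, model, rate, want_partials = FALSE) {
  edge <- en$tree$edge
  nnode <- en$ntip + en$tree$Nnode
  parts <- vector("list", nnode)
  ls <- vector("list", nnode)
  Ps <- vector("list", nrow(edge))
  for (j in seq_len(nrow(edge))) {
    ch <- edge[j, 2L]; pa <- edge[j, 1L]
    P <- transition_probabilities(model, lengths[j], rate)
    Ps[[j]] <- P
    D <- if (ch <= en$ntip) en$tipP[[ch]] else parts[[ch]]
    lsch <- if (ch <= en$ntip) 0 else ls[[ch]]
    M <- P %*% D
    if (is.null(parts[[pa]])) {
      parts[[pa]] <- M
      ls[[pa]] <- lsch
    } else {
      parts[[pa]] <- parts[[pa]] * M
      ls[[pa]] <- ls[[pa]] + lsch
    }
    f <- col_max(parts[[pa]])
    f[f <= 0 | !is.finite(f)] <- 1
    parts[[pa]] <- parts[[pa]] / rep(f, each = en$k)
    ls[[pa]] <- ls[[pa]] + log(f)
  }
  root <- edge[nrow(edge), 1L]
  lik <- colSums(model$frequencies * parts[[root]])
  out <- log(lik) + ls[[root]]
  if (want_partials) list(lnl = out, parts = parts, ls = ls, Ps = Ps, root = root)
  else out
}

# Mixture over gamma categories on the pattern scale.
#' @keywords internal
pattern_lnl <- function(en, lengths, model) {
  if (en$n_sites == 0L) return(numeric(0))
  if (en$ntip == 1L) {  # degenerate single-leaf tree: root sum only
    lik <- colSums(model$frequencies * en$tipP[[1L]])
    return(log(lik))
  }
  ncat <- length(model$rates)
  lm <- vapply(seq_len(ncat), function(c)
    prune_category(en, lengths, model, model$rates[c]) + log(model$weights[c]),
    numeric(en$npat))
  lm <- matrix(lm, nrow = en$npat)
  m <- do.call(pmax, lapply(seq_len(ncat), function(c) lm[, c]))
  out <- m + log(rowSums(exp(lm - m)))
  out[!is.finite(m)] <- -Inf
  out
}

#' Per-site log-likelihoods of an alignment on a fixed tree
#'
#' Ambiguous and missing symbols contribute partial likelihood 1 for
#' every state; sites of probability zero (e.g. conflicting states across
#' zero-length branches) return `-Inf`.
#'
#' @param aln an [alignment] whose taxa include every leaf of `tree`.
#' @param tree an [ape::phylo] with branch lengths.
#' @param model a [substitution_model] over the alignment's alphabet.
#' @return numeric vector of natural-log likelihoods, one per column.
#' @export
site_log_likelihoods <- function(aln, tree, model) {
  en <- lik_engine(aln, tree, model)
  lengths <- if (is.null(en$tree$edge.length)) numeric(0) else en$tree$edge.length
  pattern_lnl(en, lengths, model)[en$pat_index]
}

#' Total log-likelihood of an alignment on a fixed tree
#'
#' The exact sum of [site_log_likelihoods()]; zero columns give 0.
#' @inheritParams site_log_likelihoods
#' @export
tree_log_likelihood <- function(aln, tree, model) {
  sum(site_log_likelihoods(aln, tree, model))
}

# ---- branch-length optimisation ------------------------------------------

# Exclude-subtree ("upper") partial for one edge: the conditional
# likelihood of all data outside the subtree below edge j, rooted at the
# edge's parent and already weighted by the equilibrium frequencies.
# Computed per rate category from fresh post-order partials, walking the
# root-to-parent path.
#' @keywords internal
edge_flanks <- function(en, lengths, model, rate) {
  pr <- prune_category(en, lengths, model, rate, want_partials = TRUE)
  edge <- en$tree$edge
  k <- en$k; npat <- en$npat
  child_edges <- split(seq_len(nrow(edge)), edge[, 1L])
  parent_edge <- integer(en$ntip + en$tree$Nnode)
  parent_edge[edge[, 2L]] <- seq_len(nrow(edge))

  Dn <- function(v) if (v <= en$ntip) en$tipP[[v]] else pr$parts[[v]]
  lsn <- function(v) if (v <= en$ntip) 0 else pr$ls[[v]]
  Ms <- vector("list", nrow(edge))       # lazily cached P_e %*% D_child
  getM <- function(j) {
    if (is.null(Ms[[j]]))
      Ms[[j]] <<- pr$Ps[[j]] %*% Dn(edge[j, 2L])
    Ms[[j]]
  }

  U <- vector("list", en$ntip + en$tree$Nnode)       # upper partials
  lsU <- vector("list", length(U))
  U[[pr$root]] <- matrix(model$frequencies, k, npat)
  lsU[[pr$root]] <- rep(0, npat)

  upper_for_edge <- function(j) {
    pa <- edge[j, 1L]
    if (is.null(U[[pa]])) upper_for_node(pa)
    E <- U[[pa]]
    l <- lsU[[pa]]
    for (e2 in child_edges[[as.character(pa)]]) {
      if (e2 == j) next
      E <- E * getM(e2)
      l <- l + lsn(edge[e2, 2L])
    }
    f <- col_max(E); f[f <= 0 | !is.finite(f)] <- 1
    list(E = E / rep(f, each = k), ls = l + log(f))
  }
  upper_for_node <- function(v) {       # fills U[[v]] for internal v != root
    je <- parent_edge[v]
    up <- upper_for_edge(je)
    E <- crossprod(pr$Ps[[je]], up$E)
    f <- col_max(E); f[f <= 0 | !is.finite(f)] <- 1
    U[[v]] <<- E / rep(f, each = k)
    lsU[[v]] <<- up$ls + log(f)
  }
  list(upper_for_edge = upper_for_edge, Dn = Dn, lsn = lsn)
}

# Closure: total lnL as a function of the length of edge j, all other
# lengths fixed, using cached flank partials per category.
#' @keywords internal
edge_objective <- function(en, lengths, model, j) {
  ncat <- length(model$rates)
  edge <- en$tree$edge
  cache <- lapply(seq_len(ncat), function(c) {
    fl <- edge_flanks(en, lengths, model, model$rates[c])
    up <- fl$upper_for_edge(j)
    v <- edge[j, 2L]
    list(E = up$E, lsE = up$ls, D = fl$Dn(v), lsD = fl$lsn(v))
  })
  function(t) {
    lm <- vapply(seq_len(ncat), function(c) {
      cc <- cache[[c]]
      P <- transition_probabilities(model, t, model$rates[c])
      s <- colSums(cc$E * (P %*% cc$D))
      log(s) + cc$lsE + cc$lsD + log(model$weights[c])
    }, numeric(en$npat))
    lm <- matrix(lm, nrow = en$npat)
    m <- do.call(pmax, lapply(seq_len(ncat), function(c) lm[, c]))
    pat <- m + log(rowSums(exp(lm - m)))
    pat[!is.finite(m)] <- -Inf
    sum(pat * en$pat_counts)
  }
}

#' Optimise branch lengths on a fixed topology
#'
#' Coordinate ascent: each branch in turn is maximised by Brent's bounded
#' scalar search on `[min_branch, max_branch]` with all other branches
#' held fixed, using cached flanking conditional likelihoods so each
#' one-dimensional evaluation touches only the focal branch.  A proposed
#' length is accepted only if it does not decrease the likelihood, so the
#' total log-likelihood is non-decreasing across rounds.  Iteration stops
#' when a full round improves the log-likelihood by less than `tol`.
#'
#' @inheritParams site_log_likelihoods
#' @param tol convergence tolerance on the round-to-round log-likelihood
#'   improvement.
#' @param max_rounds maximum coordinate-ascent rounds.
#' @param min_branch,max_branch search bounds for every branch length.
#' @return the input tree (post-order edge ordering) with optimised
#'   branch lengths; attribute `log_likelihood` carries the final lnL.
#' @export
optimize_branch_lengths <- function(aln, tree, model, tol = 1e-6,
                                    max_rounds = 50L,
                                    min_branch = 1e-8, max_branch = 20) {
  en <- lik_engine(aln, tree, model)
  if (en$ntip < 2L || en$n_sites == 0L) {
    attr(tree, "log_likelihood") <- tree_log_likelihood(aln, tree, model)
    return(tree)
  }
  lengths <- pmax(en$tree$edge.length, min_branch)
  cur <- sum(pattern_lnl(en, lengths, model) * en$pat_counts)
  if (!is.finite(cur))
    optimization_error("non-finite log-likelihood at starting branch lengths (lnL = %s)", cur)
  for (round in seq_len(max_rounds)) {
    for (j in seq_along(lengths)) {
      obj <- edge_objective(en, lengths, model, j)
      now <- obj(lengths[j])
      opt <- stats::optimize(obj, c(min_branch, max_branch),
                             maximum = TRUE, tol = 1e-6)
      if (opt$objective > now) lengths[j] <- opt$maximum
    }
    new <- sum(pattern_lnl(en, lengths, model) * en$pat_counts)
    if (new - cur < tol) { cur <- max(cur, new); break }
    cur <- new
  }
  out <- en$tree
  out$edge.length <- lengths
  attr(out, "log_likelihood") <- cur
  out
}

#' Estimate the gamma shape parameter by profile likelihood
#'
#' Alternates bounded one-dimensional search on the shape `alpha` with
#' optional branch-length re-optimisation.
#'
#' @inheritParams optimize_branch_lengths
#' @param interval search interval for alpha.
#' @param optimize_branches re-optimise branch lengths at each round.
#' @param rounds alternation rounds.
#' @return list with `alpha`, `tree` (with optimised lengths if
#'   requested), `model` (updated shape) and `log_likelihood`.
#' @export
estimate_gamma_shape <- function(aln, tree, model, interval = c(0.02, 100),
                                 optimize_branches = TRUE, rounds = 2L) {
  cur_tree <- tree
  cur_model <- model
  for (r in seq_len(rounds)) {
    if (optimize_branches)
      cur_tree <- optimize_branch_lengths(aln, cur_tree, cur_model)
    en <- lik_engine(aln, cur_tree, cur_model)
    lengths <- en$tree$edge.length
    f <- function(a) {
      m <- set_gamma_shape(cur_model, a)
      sum(pattern_lnl(en, lengths, m) * en$pat_counts)
    }
    opt <- stats::optimize(f, interval, maximum = TRUE, tol = 1e-4)
    cur_model <- set_gamma_shape(cur_model, opt$maximum)
  }
  if (optimize_branches)
    cur_tree <- optimize_branch_lengths(aln, cur_tree, cur_model)
  list(alpha = cur_model$alpha, tree = cur_tree, model = cur_model,
       log_likelihood = tree_log_likelihood(aln, cur_tree, cur_model))
}

#' Per-partition site log-likelihoods under per-partition models
#'
#' Evaluates each partition of a concatenated alignment under its own
#' substitution model on a shared (linked) set of branch lengths and
#' returns the full-length per-site log-likelihood vector.
#'
#' @inheritParams site_log_likelihoods
#' @param pm a [partition_map] covering the alignment.
#' @param models a single [substitution_model] or a list with one model
#'   per partition.
#' @export
partitioned_site_log_likelihoods <- function(aln, tree, pm, models) {
  if (inherits(models, "substitution_model"))
    models <- rep(list(models), nrow(pm))
  if (length(models) != nrow(pm))
    value_error("need one model per partition (%d != %d)",
                length(models), nrow(pm))
  out <- numeric(ncol(aln))
  ab <- attr(aln, "alphabet")
  for (i in seq_len(nrow(pm))) {
    cols <- partition_columns(pm, i)
    sub <- alignment(unclass(aln)[, cols, drop = FALSE], ab)
    out[cols] <- site_log_likelihoods(sub, tree, models[[i]])
  }
  out
}
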