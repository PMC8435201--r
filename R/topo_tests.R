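# Likelihood-based topology hypothesis tests over a candidate tree set:
# the delta-lnL statistic (both printed conventions), the RELL bootstrap
# of per-site log-likelihoods, the approximately unbiased (AU) test via
# the multiscale bootstrap, and BIC-approximation posterior probabilities.

#' Likelihood-ratio statistic between a null and an alternate tree
#'
#' Two conventions are provided because published tables commonly print
#' `lnL(T0) - lnL(TA)` (positive when the null fits better) while the
#' accompanying formula is often `2 * (lnL(TA) - lnL(T0))`.  `"table"`
#' returns the former, `"equation"` the latter; no attempt is made to
#' guess which a given source intended.
#'
#' @param lnl_null,lnl_alt finite total log-likelihoods.
#' @param convention `"table"` or `"equation"`.
#' @export
delta_lnl <- function(lnl_null, lnl_alt, convention = c("table", "equation")) {
  if (!is.finite(lnl_null) || !is.finite(lnl_alt))
    value_error("log-likelihoods must be finite")
  convention <- match.arg(convention)
  switch(convention,
         table = lnl_null - lnl_alt,
         equation = 2 * (lnl_alt - lnl_null))
}

#' RELL bootstrap of per-site log-likelihoods
#'
#' Resampling of estimated log-likelihoods: each replicate resamples
#' `n_sites` site indices with replacement (as multinomial site weights,
#' which is distributionally identical and fast) and applies the *same*
#' resample to every tree, so replicate differences estimate the variance
#' of tree log-likelihood differences.
#'
#' @param site_lnl trees x sites matrix of per-site log-likelihoods.
#' @param n_boot number of bootstrap replicates.
#' @param seed optional RNG seed for reproducibility.
#' @return trees x n_boot matrix of replicate total log-likelihoods.
#' @export
rell_bootstrap <- function(site_lnl, n_boot = 10000L, seed = NULL) {
  m <- as.matrix(site_lnl)
  n <- ncol(m)
  if (n < 1L || nrow(m) < 1L) value_error("empty site log-likelihood matrix")
  if (n_boot < 1L) value_error("n_boot must be >= 1")
  with_seed(seed, {
    out <- matrix(0, nrow(m), n_boot, dimnames = list(rownames(m), NULL))
    chunk <- max(1L, min(n_boot, floor(2e7 / n)))
    done <- 0L
    while (done < n_boot) {
      b <- min(chunk, n_boot - done)
      w <- stats::rmultinom(b, n, rep(1 / n, n))
      out[, done + seq_len(b)] <- m %*% w
      done <- done + b
    }
    out
  })
}

#' Approximately unbiased (AU) test from a site log-likelihood matrix
#'
#' Multiscale bootstrap: at each scale factor `r` the sites are resampled
#' to size `ceiling(r * n_sites)` and the proportion of replicates in
#' which each tree attains the maximum total is recorded (ties broken
#' uniformly at random).  The normal-quantile-transformed proportions are
#' regressed on `(sqrt(r), 1/sqrt(r))` by weighted least squares with
#' binomial variance weights, giving the signed distance `d` and boundary
#' curvature `c`; the AU p-value is `1 - pnorm(d - c)`.
#'
#' Degenerate proportions of exactly 0 or 1 at a scale are replaced by
#' `1/(2B)` and `1 - 1/(2B)` before the transform.  A tree whose
#' proportion saturates at every scale (it wins or loses every replicate
#' at every scale) lies so far from the hypothesis boundary that the
#' regression is uninformative; its p-value is reported as 1 or 0
#' directly.  With a single scale the fit reduces to the naive bootstrap
#' proportion.
#'
#' @inheritParams rell_bootstrap
#' @param scales positive scale factors; must contain 1.0.
#' @param n_boot_per_scale bootstrap replicates per scale.
#' @return named vector of AU p-values (one per tree) with attributes
#'   `bp` (trees x scales proportion matrix), `d` and `c`.
#' @export
au_test <- function(site_lnl, scales = seq(0.5, 1.4, by = 0.1),
                    n_boot_per_scale = 1000L, seed = NULL) {
  m <- as.matrix(site_lnl)
  ntree <- nrow(m); n <- ncol(m)
  if (ntree < 2L) value_error("AU test needs at least 2 trees")
  if (n < 1L) value_error("empty site log-likelihood matrix")
  if (any(scales <= 0)) value_error("scales must be positive")
  if (!any(abs(scales - 1) < 1e-12))
    value_error("scales must contain 1.0")
  B <- as.integer(n_boot_per_scale)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("tree", seq_len(ntree))
  with_seed(seed, {
    bp <- matrix(NA_real_, ntree, length(scales),
                 dimnames = list(ids, paste0("r", scales)))
    for (si in seq_along(scales)) {
      nr <- as.integer(ceiling(scales[si] * n))
      w <- stats::rmultinom(B, nr, rep(1 / n, n))
      tot <- m %*% w
      best <- max.col(t(tot), ties.method = "random")
      bp[, si] <- tabulate(best, ntree) / B
    }
    p <- numeric(ntree)
    dvec <- cvec <- rep(NA_real_, ntree)
    for (i in seq_len(ntree)) {
      b <- bp[i, ]
      if (all(b == 1)) { p[i] <- 1; next }
      if (all(b == 0)) { p[i] <- 0; next }
      if (length(scales) == 1L) { p[i] <- b; next }
      b <- pmin(pmax(b, 1 / (2 * B)), 1 - 1 / (2 * B))
      y <- stats::qnorm(1 - b)
      X <- cbind(sqrt(scales), 1 / sqrt(scales))
      wt <- B * stats::dnorm(y)^2 / (b * (1 - b))
      fit <- stats::lm.wfit(X, y, wt)
      dvec[i] <- fit$coefficients[1]; cvec[i] <- fit$coefficients[2]
      p[i] <- 1 - stats::pnorm(dvec[i] - cvec[i])
    }
    names(p) <- ids
    structure(p, bp = bp, d = dvec, c = cvec)
  })
}

#' BIC-approximation posterior probabilities over candidate trees
#'
#' Posterior of tree i proportional to `exp(lnL_i - penalty_i / 2)`,
#' computed through a max-shifted log-sum-exp.  With equal penalty terms
#' (same parameter dimension for every fully resolved candidate, the
#' default) the penalties cancel and the posterior is a softmax of the
#' log-likelihoods.
#'
#' @param tree_lnls finite total log-likelihoods.
#' @param penalty_terms per-tree BIC penalties (`k * log(n)`); a scalar is
#'   recycled, default 0 (equal penalties).
#' @return posterior probabilities summing to 1.
#' @export
bic_posteriors <- function(tree_lnls, penalty_terms = 0) {
  if (length(tree_lnls) < 1L) value_error("need at least one tree")
  if (any(!is.finite(tree_lnls))) value_error("log-likelihoods must be finite")
  pen <- rep_len(penalty_terms, length(tree_lnls))
  s <- tree_lnls - pen / 2
  w <- exp(s - max(s))
  out <- w / sum(w)
  names(out) <- names(tree_lnls)
  out
}

#' Run the full topology-testing stage over a candidate tree set
#'
#' For each candidate tree: optimises branch lengths on the fixed
#' topology, computes per-site log-likelihoods, then the likelihood-ratio
#' statistic against the null tree (both conventions), AU p-values from
#' the multiscale bootstrap and BIC posterior probabilities.
#'
#' @inheritParams site_log_likelihoods
#' @param trees named list of candidate [ape::phylo] trees (or a
#'   `multiPhylo`); names become tree ids.
#' @param null_id id of the null-hypothesis tree (default: the first).
#' @param n_boot RELL bootstrap replicates recorded in the metadata and
#'   used for the scale-1 bootstrap.
#' @param scales AU multiscale factors.
#' @param n_boot_per_scale AU replicates per scale.
#' @param seed seed controlling all resampling.
#' @param optimize optimise branch lengths per tree before evaluation.
#' @return a `topology_test_result` data frame with one row per tree:
#'   `tree`, `lnl`, `delta_table`, `delta_equation`, `au_p`,
#'   `bic_posterior`; metadata (null id, B, scales, seed) in attributes,
#'   the site log-likelihood matrix in attribute `site_lnl`.
#' @export
run_topology_tests <- function(aln, trees, model, null_id = NULL,
                               n_boot = 10000L,
                               scales = seq(0.5, 1.4, by = 0.1),
                               n_boot_per_scale = 1000L,
                               seed = NULL, optimize = TRUE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- as.list(trees)
  if (is.null(names(trees)) || any(!nzchar(names(trees))))
    names(trees) <- paste0("T", seq_along(trees) - 1L)
  ids <- names(trees)
  if (is.null(null_id)) null_id <- ids[1]
  if (!null_id %in% ids) value_error("null tree '%s' not in candidate set", null_id)
  rows <- lapply(trees, function(tr) {
    if (optimize) tr <- optimize_branch_lengths(aln, tr, model)
    site_log_likelihoods(aln, tr, model)
  })
  sl <- site_lnl_matrix(do.call(rbind, rows), ids, check_nonpositive = FALSE)
  lnls <- rowSums(sl)
  au <- au_test(sl, scales = scales, n_boot_per_scale = n_boot_per_scale,
                seed = if (is.null(seed)) NULL else derive_seed(seed, "au"))
  bic <- bic_posteriors(lnls)
  res <- data.frame(
    tree = ids,
    lnl = as.numeric(lnls),
    delta_table = vapply(ids, function(i)
      delta_lnl(lnls[null_id], lnls[i], "table"), 0),
    delta_equation = vapply(ids, function(i)
      delta_lnl(lnls[null_id], lnls[i], "equation"), 0),
    au_p = as.numeric(au),
    bic_posterior = as.numeric(bic),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, null_id = null_id, n_boot = n_boot, scales = scales,
            n_boot_per_scale = n_boot_per_scale, seed = seed,
            site_lnl = sl, class = c("topology_test_result", "data.frame"))
}
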