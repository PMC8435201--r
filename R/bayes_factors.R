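# Marginal likelihoods from MCMC log-likelihood traces via the (moving)
# harmonic-mean estimator, Bayes factors and evidence classification.
#
# The harmonic-mean estimator is computed entirely in log space:
# log HM = -(logsumexp(-lnL) - log n).  It is a known upwardly biased,
# high-variance estimator of the log marginal likelihood; the moving
# version tracks its stabilisation along the chain.

#' Construct an MCMC log-likelihood trace
#'
#' @param lnl numeric log-likelihood samples (post any burn-in/thinning
#'   already applied when constructed directly).
#' @param cycles strictly increasing cycle indices (default `1..n`).
#' @param chain_id chain label.
#' @param burn_in,thin bookkeeping of how the trace was derived.
#' @return object of class `mcmc_trace`.
#' @export
mcmc_trace <- function(lnl, cycles = seq_along(lnl), chain_id = "chain1",
                       burn_in = 0L, thin = 1L) {
  if (length(lnl) < 1L) value_error("trace needs at least one sample")
  if (length(cycles) != length(lnl))
    value_error("cycles and samples differ in length")
  if (any(diff(cycles) <= 0)) value_error("cycle indices must strictly increase")
  structure(list(chain_id = chain_id, cycles = as.integer(cycles),
                 lnl = as.numeric(lnl), burn_in = as.integer(burn_in),
                 thin = as.integer(thin)),
            class = "mcmc_trace")
}

#' @export
print.mcmc_trace <- function(x, ...) {
  cat(sprintf("mcmc_trace '%s': %d samples (burn-in %d, thin %d), lnL %.2f..%.2f\n",
              x$chain_id, length(x$lnl), x$burn_in, x$thin,
              min(x$lnl), max(x$lnl)))
  invisible(x)
}

#' Read an MCMC trace file
#'
#' Tab/whitespace-separated table with a header row, one sample per row
#' (the trace dialect of common Bayesian phylogenetics programs).  The
#' first `burn_in` rows are discarded, then every `thin`-th remaining row
#' is kept (starting with the first).
#'
#' @param path file path.
#' @param lnl_column log-likelihood column, by name or index.
#' @param burn_in rows to discard from the start.
#' @param thin keep every `thin`-th post-burn-in row.
#' @param chain_id chain label (default: file base name).
#' @export
read_trace <- function(path, lnl_column = "loglik", burn_in = 0L, thin = 1L,
                       chain_id = NULL) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (is.character(lnl_column)) {
    if (!lnl_column %in% names(tab))
      format_error("column '%s' not found (have: %s)", lnl_column,
                   paste(names(tab), collapse = ", "))
    lnl <- tab[[lnl_column]]
  } else {
    if (lnl_column < 1L || lnl_column > ncol(tab))
      format_error("column index %d out of range", lnl_column)
    lnl <- tab[[lnl_column]]
  }
  if (!is.numeric(lnl)) format_error("log-likelihood column is not numeric")
  n <- length(lnl)
  if (burn_in >= n) value_error("burn-in (%d) >= number of rows (%d)", burn_in, n)
  if (thin < 1L) value_error("thin must be >= 1")
  keep <- seq.int(burn_in + 1L, n, by = thin)
  mcmc_trace(lnl[keep], cycles = keep,
             chain_id = chain_id %||% tools::file_path_sans_ext(basename(path)),
             burn_in = burn_in, thin = thin)
}

#' Pool post-burn-in samples across chains
#'
#' Concatenates traces in chain order, retaining provenance.
#'
#' @param traces list of [mcmc_trace] objects (a single trace is
#'   accepted).
#' @return numeric vector of pooled log-likelihood samples with attribute
#'   `provenance` (data frame of chain/cycle per sample).
#' @export
pool_chains <- function(traces) {
  if (inherits(traces, "mcmc_trace")) traces <- list(traces)
  if (length(traces) == 0L) value_error("no traces to pool")
  lnl <- unlist(lapply(traces, `[[`, "lnl"), use.names = FALSE)
  prov <- do.call(rbind, lapply(traces, function(tr)
    data.frame(chain = tr$chain_id, cycle = tr$cycles,
               stringsAsFactors = FALSE)))
  structure(lnl, provenance = prov)
}

#' Log harmonic-mean estimator of the marginal likelihood
#'
#' Returns `-(logsumexp(-lnL) - log n)`, the natural log of the harmonic
#' mean of the sampled likelihoods, computed without leaving log space so
#' traces spanning thousands of log units neither overflow nor underflow.
#'
#' @param lnl_samples finite log-likelihood samples (n >= 1).
#' @export
log_harmonic_mean <- function(lnl_samples) {
  x <- as.numeric(lnl_samples)
  if (length(x) < 1L) value_error("need at least one sample")
  if (any(!is.finite(x))) value_error("non-finite log-likelihood sample")
  m <- max(-x)                      # max-shift; exact for constant traces
  -(m + log(mean(exp(-x - m))))
}

#' Moving harmonic-mean estimator along a trace
#'
#' At cycle `i` (1-based over the post-burn-in sample sequence) the
#' estimate is the log harmonic mean of the most recent
#' `ceiling(window_fraction * i)` samples (window minimum 1, so the first
#' cycle is defined); the series advances with a step length of `step`.
#' The final series value is the reported point estimate.
#'
#' @param trace an [mcmc_trace] or numeric vector of pooled samples.
#' @param window_fraction window size as a fraction of the current cycle,
#'   in (0, 1].
#' @param step emit an estimate every `step` cycles (the last cycle is
#'   always included).
#' @return object of class `marginal_likelihood_estimate`: list with
#'   `log_marginal` (point estimate), `series` (data frame cycle /
#'   window / estimate), `n_samples`, `window_fraction`.
#' @export
moving_harmonic_mean <- function(trace, window_fraction = 0.33, step = 1L) {
  x <- if (inherits(trace, "mcmc_trace")) trace$lnl else as.numeric(trace)
  n <- length(x)
  if (n < 1L) value_error("need at least one sample")
  if (window_fraction <= 0 || window_fraction > 1)
    value_error("window_fraction must be in (0, 1]")
  cycles <- unique(c(seq.int(1L, n, by = as.integer(step)), n))
  win <- pmax(1L, as.integer(ceiling(window_fraction * cycles)))
  est <- vapply(seq_along(cycles), function(j) {
    i <- cycles[j]
    log_harmonic_mean(x[(i - win[j] + 1L):i])
  }, 0)
  structure(list(
    log_marginal = est[length(est)],
    series = data.frame(cycle = cycles, window = win, estimate = est),
    n_samples = n, window_fraction = window_fraction),
    class = "marginal_likelihood_estimate")
}

#' @export
print.marginal_likelihood_estimate <- function(x, ...) {
  cat(sprintf("moving harmonic-mean marginal likelihood: %.4f (n = %d, window fraction %.2f)\n",
              x$log_marginal, x$n_samples, x$window_fraction))
  invisible(x)
}

#' Bayes factor between two marginal likelihoods
#'
#' The default `"log-of-difference"` formula is
#' `BF10 = 2 * ln(m1 - m0)` for `m1 > m0` and `-2 * ln(m0 - m1)` for
#' `m1 < m0`, i.e. the log is taken of the absolute difference of the two
#' log marginal likelihoods and the sign of the difference is re-applied.
#' This non-standard transformation reproduces published values of the
#' form `2*ln(delta)`; the conventional `BF10 = 2 * (m1 - m0)` is
#' available as `formula = "standard"`.  A zero difference yields BF = 0
#' with a warning (category "none") rather than an error.
#'
#' @param marginal_t1,marginal_t0 finite log marginal likelihoods of the
#'   alternate (T1) and null (T0) hypotheses (or
#'   `marginal_likelihood_estimate` objects).
#' @param formula `"log-of-difference"` (default) or `"standard"`.
#' @param model label of the substitution model the traces were sampled
#'   under (metadata only).
#' @return object of class `bayes_factor_result`: list with `bf`,
#'   `delta` (m1 - m0), `marginal_t1`, `marginal_t0`, `formula`,
#'   `model`, `direction` (`"favors T1"` / `"favors T0"` / `"none"`)
#'   and `evidence` (see [classify_evidence()]).
#' @export
bayes_factor <- function(marginal_t1, marginal_t0,
                         formula = c("log-of-difference", "standard"),
                         model = NA_character_) {
  g <- function(m) if (inherits(m, "marginal_likelihood_estimate")) m$log_marginal else m
  m1 <- g(marginal_t1); m0 <- g(marginal_t0)
  if (!is.finite(m1) || !is.finite(m0))
    value_error("marginal likelihoods must be finite")
  formula <- match.arg(formula)
  delta <- m1 - m0
  if (delta == 0) {
    warning("equal marginal likelihoods: Bayes factor undefined under the log-of-difference formula, reporting 0")
    bf <- 0
  } else if (formula == "standard") {
    bf <- 2 * delta
  } else {
    bf <- sign(delta) * 2 * log(abs(delta))
  }
  direction <- if (delta > 0) "favors T1" else if (delta < 0) "favors T0" else "none"
  structure(list(bf = bf, delta = delta, marginal_t1 = m1, marginal_t0 = m0,
                 formula = formula, model = model, direction = direction,
                 evidence = classify_evidence(bf)),
            class = "bayes_factor_result")
}

#' @export
print.bayes_factor_result <- function(x, ...) {
  cat(sprintf("BF10 = %.4g (%s formula): %s evidence, %s\n",
              x$bf, x$formula, x$evidence, x$direction))
  invisible(x)
}

#' Classify Bayes-factor evidence strength
#'
#' Jeffreys-style bands on the magnitude: `|BF| < 2` none, `2 <= |BF| < 6`
#' some, `6 <= |BF| < 10` strong, `|BF| >= 10` very strong.  The sign
#' (direction of support) is carried separately by [bayes_factor()].
#'
#' @param bf finite Bayes factor.
#' @return one of `"none"`, `"some"`, `"strong"`, `"very strong"`.
#' @export
classify_evidence <- function(bf) {
  if (!is.finite(bf)) value_error("Bayes factor must be finite")
  a <- abs(bf)
  if (a < 2) "none"
  else if (a < 6) "some"
  else if (a < 10) "strong"
  else "very strong"
}
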