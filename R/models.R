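# Substitution models: empirical amino-acid exchangeability matrices
# (LG, WAG, MtZoa; sourced from phangorn's model tables), the equal-rates
# Poisson model for arbitrary alphabets, discrete-gamma rate categories
# and empirical ("+F") equilibrium frequencies.
#
# The rate matrix is the standard GTR construction Q = S diag(pi) with
# the diagonal set so rows sum to zero, normalised so the expected
# substitution rate at stationarity is one: sum_i pi_i * (-Q_ii) = 1.
# Branch lengths are therefore in expected substitutions per site.

#' Discrete-gamma rate categories
#'
#' Mean-per-category discretisation of a Gamma(shape = alpha, rate =
#' alpha) distribution into `n_categories` equal-probability bins
#' (category rate = conditional mean between quantile cut points).  The
#' category-weighted mean rate is exactly 1.
#'
#' @param alpha gamma shape (> 0); small values = strong among-site rate
#'   heterogeneity, large values approach rate homogeneity.
#' @param n_categories number of categories (>= 1).
#' @return list with `rates` and `weights` (both length `n_categories`).
#' @export
discrete_gamma_rates <- function(alpha, n_categories = 4L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    value_error("alpha must be a single positive number")
  n <- as.integer(n_categories)
  if (n < 1L) value_error("n_categories must be >= 1")
  if (n == 1L) return(list(rates = 1, weights = 1))
  cuts <- stats::qgamma(seq(0, 1, length.out = n + 1L), shape = alpha, rate = alpha)
  # E[X | a < X < b] for X ~ Gamma(alpha, alpha) via the alpha+1 identity
  upper <- stats::pgamma(cuts[-1L], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(cuts[-(n + 1L)], shape = alpha + 1, rate = alpha)
  rates <- (upper - lower) * n
  rates <- rates / sum(rates / n)  # enforce weighted mean exactly 1
  list(rates = rates, weights = rep(1 / n, n))
}

#' Empirical equilibrium frequencies from an alignment ("+F")
#'
#' Observed relative frequencies of unambiguous residues.  States unseen
#' in the data receive a pseudo-frequency of `1 / (2 * total residues)`
#' before renormalisation, so small alignments never yield zero
#' stationary probabilities.
#'
#' @param aln an [alignment].
#' @return named frequency vector over the alphabet's states.
#' @export
empirical_frequencies <- function(aln) {
  ab <- attr(aln, "alphabet")
  counts <- table(factor(unclass(aln), levels = ab$states))
  total <- sum(counts)
  if (total == 0L) value_error("alignment contains no unambiguous residues")
  freq <- as.numeric(counts) / total
  pseudo <- 1 / (2 * total)
  freq[freq == 0] <- pseudo
  freq <- freq / sum(freq)
  names(freq) <- ab$states
  freq
}

#' @keywords internal
preset_exchangeabilities <- function(name, k) {
  if (name %in% c("Poisson", "equal")) {
    s <- matrix(1, k, k); diag(s) <- 0
    return(list(exch = s, freq = rep(1 / k, k)))
  }
  key <- c(LG = ".LG", WAG = ".WAG", MtZoa = ".MtZoa")[name]
  if (is.na(key)) value_error("unknown model preset '%s'", name)
  mod <- get(key, envir = asNamespace("phangorn"))
  s <- matrix(0, 20, 20)
  s[lower.tri(s)] <- mod$Q            # column-major lower triangle,
  s <- s + t(s)                       # ARNDCQEGHILKMFPSTWYV order
  freq <- as.numeric(mod$bf)
  list(exch = s, freq = freq / sum(freq))
}

#' Construct a substitution model
#'
#' @param exchangeabilities `"LG"`, `"WAG"`, `"MtZoa"`, `"Poisson"`
#'   (equal rates, any alphabet) or a symmetric non-negative k x k matrix
#'   with zero diagonal.
#' @param frequencies equilibrium frequencies; `NULL` uses the preset's
#'   own frequencies (uniform for Poisson/custom).  Pass
#'   [empirical_frequencies()] output for "+F" models.
#' @param alpha gamma shape for among-site rate heterogeneity ("+G").
#' @param n_rate_categories discrete gamma categories (1 = no
#'   heterogeneity; default 4).
#' @param alphabet alphabet the model operates on (`"aa"`, `"dna"`,
#'   `"generic"`); defaults to `"aa"` for the empirical presets.
#' @param symbols state symbols for a generic alphabet.
#' @return object of class `substitution_model` with the normalised rate
#'   matrix and a cached symmetric eigendecomposition.
#' @export
substitution_model <- function(exchangeabilities = "LG", frequencies = NULL,
                               alpha = 1.0, n_rate_categories = 4L,
                               alphabet = NULL, symbols = NULL) {
  if (is.character(exchangeabilities)) {
    name <- exchangeabilities
    if (is.null(alphabet)) alphabet <- if (name == "Poisson" && !is.null(symbols)) "generic" else "aa"
    ab <- alphabet_spec(alphabet, symbols)
    k <- length(ab$states)
    if (name %in% c("LG", "WAG", "MtZoa") && k != 20L)
      value_error("%s is an amino-acid model (k = 20)", name)
    preset <- preset_exchangeabilities(name, k)
    s <- preset$exch
    if (is.null(frequencies)) frequencies <- preset$freq
  } else {
    name <- "custom"
    s <- as.matrix(exchangeabilities)
    if (is.null(alphabet)) alphabet <- "generic"
    ab <- alphabet_spec(alphabet,
                        symbols %||% LETTERS[seq_len(nrow(s))])
    k <- length(ab$states)
    if (nrow(s) != k || ncol(s) != k)
      value_error("exchangeability matrix must be %d x %d", k, k)
    if (any(abs(s - t(s)) > 1e-12) || any(s < 0) || any(diag(s) != 0))
      value_error("exchangeabilities must be symmetric, non-negative, zero-diagonal")
    if (is.null(frequencies)) frequencies <- rep(1 / k, k)
  }
  pi <- as.numeric(frequencies)
  if (length(pi) != k) value_error("frequencies must have length %d", k)
  if (any(pi <= 0)) value_error("all equilibrium frequencies must be > 0")
  pi <- pi / sum(pi)
  stopifnot(abs(sum(pi) - 1) < 1e-12)

  q <- s %*% diag(pi)
  diag(q) <- -rowSums(q)
  mu <- -sum(pi * diag(q))           # expected rate at stationarity
  q <- q / mu                        # branch lengths in subst./site
  sp <- sqrt(pi)
  b <- diag(sp) %*% q %*% diag(1 / sp)
  b <- (b + t(b)) / 2                # exactly symmetric for eigen()
  eig <- eigen(b, symmetric = TRUE)
  g <- discrete_gamma_rates(alpha, n_rate_categories)

  structure(list(
    name = name, alphabet = ab, k = k,
    exchangeabilities = s, frequencies = stats::setNames(pi, ab$states),
    Q = q, alpha = alpha, n_rate_categories = as.integer(n_rate_categories),
    rates = g$rates, weights = g$weights,
    eigen = list(values = eig$values,
                 right = diag(1 / sp) %*% eig$vectors,
                 left = t(eig$vectors) %*% diag(sp))
  ), class = "substitution_model")
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("substitution model: %s (+G alpha=%g, %d categories), k=%d states\n",
              x$name, x$alpha, x$n_rate_categories, x$k))
  invisible(x)
}

#' Replace the gamma shape of a model, keeping everything else
#' @param model a [substitution_model].
#' @param alpha new gamma shape.
#' @export
set_gamma_shape <- function(model, alpha) {
  g <- discrete_gamma_rates(alpha, model$n_rate_categories)
  model$alpha <- alpha
  model$rates <- g$rates
  model$weights <- g$weights
  model
}

#' Transition probability matrix P = exp(Q t r)
#'
#' Computed from the cached symmetric eigendecomposition of the
#' frequency-weighted rate matrix.  `t = 0` returns the exact identity so
#' that impossible zero-length conflicts yield likelihood exactly 0.
#' Entries in `[-1e-12, 0)` from round-off are clipped to 0.
#'
#' @param model a [substitution_model].
#' @param branch_length branch length (>= 0, substitutions per site).
#' @param rate rate multiplier (> 0), e.g. a gamma category rate.
#' @return k x k row-stochastic matrix.
#' @export
transition_probabilities <- function(model, branch_length, rate = 1) {
  if (branch_length < 0) value_error("branch length must be >= 0")
  if (rate <= 0) value_error("rate must be > 0")
  t <- branch_length * rate
  if (t == 0) return(diag(model$k))
  e <- model$eigen
  p <- e$right %*% (exp(e$values * t) * e$left)
  p[p < 0] <- 0
  p
}
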