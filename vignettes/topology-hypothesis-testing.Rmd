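---
title: "Discriminating phylogenetic tree topologies: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating phylogenetic tree topologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topotestr)
```

## The problem

Deep phylogenetic relationships — such as which lineage is sister to the
rest of a rapidly radiating clade — often cannot be settled by a single
tree search. The question is better posed as hypothesis discrimination:
given a fixed set of candidate topologies (e.g. a Bayesian consensus
tree, a maximum-likelihood tree, and previously published alternatives),
how strongly does a concatenated multi-locus alignment prefer one over
the others?

`topotestr` implements that discrimination stage end to end for
target-capture supermatrices: a fixed-topology likelihood engine,
site-likelihood resampling tests (likelihood ratios, RELL bootstrap, AU
test, BIC posteriors), marginal-likelihood estimation from MCMC traces
with Bayes-factor evidence classification, supermatrix occupancy
statistics, and the upstream bait-design filter used to build such
datasets. A synthetic-data module generates inputs with the statistical
structure the analysis assumes, so every stage is testable without any
external download.

## The likelihood model

Site likelihoods are computed under standard time-reversible amino-acid
(or nucleotide/generic) substitution models. The rate matrix is
$Q = S\,\mathrm{diag}(\pi)$ with symmetric exchangeabilities $S$ (named
presets LG, WAG, MtZoa, or the equal-rates Poisson model), diagonal set
so rows sum to zero, and normalised so
$\sum_i \pi_i (-Q_{ii}) = 1$ — branch lengths are therefore in expected
substitutions per site. Among-site rate heterogeneity ("+G") uses the
discrete-gamma approximation with *mean-per-category* rates
(4 equal-weight categories by default; category means rather than
medians, so the weighted mean rate is exactly 1 for any shape
$\alpha$). Equilibrium frequencies can be the preset's own or observed
from the data ("+F", `empirical_frequencies()`); unobserved states get a
pseudo-frequency of $1/(2\,N_{\text{residues}})$ before renormalisation,
which keeps likelihoods finite on small fixtures without materially
moving frequencies at realistic sample sizes.

Per-site log-likelihoods use Felsenstein pruning over a post-order
traversal with three numerical safeguards:

* columns are compressed to unique site patterns before pruning;
* conditional likelihoods are rescaled at every node (per-site log
  scalers), so deep trees cannot underflow — impossible sites return
  exactly `-Inf` rather than noise;
* $P(t) = e^{Qt}$ comes from a cached symmetric eigendecomposition of
  the $\pi$-weighted rate matrix, with $t = 0$ special-cased to the
  exact identity matrix (so conflicting states across zero-length
  branches give probability exactly zero) and round-off entries in
  $[-10^{-12}, 0)$ clipped to zero.

Fully ambiguous symbols (`X`, `?`, `-` for amino acids; `N`, `?`, `-`
for nucleotides) contribute partial likelihood 1 for every state;
trimmed supermatrices mix all three, so no distinction is drawn between
gap and missing.

By time reversibility the likelihood is invariant to the root placement
(the pulley principle); the test suite asserts this to $10^{-10}$
alongside agreement with exhaustive internal-state enumeration on all
three unrooted quartet topologies.

### Branch-length optimisation

Candidate topologies are inputs; only branch lengths are free.
`optimize_branch_lengths()` performs coordinate ascent: each branch in
turn is maximised by Brent's bounded scalar search on
$[10^{-8}, 20]$ substitutions/site, using flanking conditional
likelihoods (the subtree below the branch and the frequency-weighted
partial for everything outside it) so each one-dimensional evaluation
touches only the focal branch. Partials are recomputed exactly before
each branch update, and a proposed length is accepted only if it does
not decrease the likelihood — the total log-likelihood is therefore
non-decreasing across rounds, and iteration stops when a full round
gains less than `tol` (default $10^{-6}$ log units) or after
`max_rounds` (50). No analytic derivatives are used; robustness was
preferred over speed at the problem sizes this package targets.

The gamma shape is not optimised during branch-length fitting;
`estimate_gamma_shape()` profiles $\alpha$ by bounded search, alternating
with branch-length re-optimisation. Partitioned data are evaluated by
summing per-partition log-likelihoods under per-partition models with
*linked* (shared) branch lengths, the common partitioned-analysis
default; the alternative of unlinked lengths is out of scope.

## Topology tests

All tests operate on the trees × sites matrix of per-site
log-likelihoods (`site_lnl_matrix`), so they can equally be fed from
this package's engine or from per-site output of external ML programs
(`read_site_lnl_matrix()` accepts both this package's TSV and the common
`n_trees n_sites`-headed dialect).

**Likelihood ratio.** `delta_lnl()` implements two conventions, because
published comparison tables commonly print
$\ln L(T_0) - \ln L(T_A)$ (positive when the null fits best) while the
printed defining equation is often $2(\ln L(T_A) - \ln L(T_0))$. Both
are reported; the package does not guess which a given source intended.

**RELL bootstrap.** Each replicate resamples `n_sites` sites with
replacement and applies the *same* resample to every tree (paired
resampling — RELL variance is the variance of differences, so pairing is
essential). Resampling is implemented as multinomial site weights,
distributionally identical to index resampling and much faster; 10,000
replicates is the default.

**AU test.** The multiscale bootstrap: at each scale
$r \in \{0.5, 0.6, \ldots, 1.4\}$ (the de-facto standard set) sites are
resampled to size $\lceil r\,n \rceil$ and the proportion of replicates
in which each tree is the maximum is recorded, with exact ties broken
uniformly at random under the run's seed (this preserves the symmetric
$p \approx 0.5$ answer for identical trees). The
normal-quantile-transformed proportions are fitted by weighted least
squares against $(\sqrt{r}, 1/\sqrt{r})$ with binomial variance
weights, giving signed distance $d$ and curvature $c$;
$p_{AU} = 1 - \Phi(d - c)$.

Two degenerate regimes need explicit rules. Proportions of exactly 0 or
1 at a single scale are replaced by $1/(2B)$ and $1 - 1/(2B)$ before the
transform, keeping it finite without discarding scales. But a tree that
wins (or loses) *every* replicate at *every* scale lies so far from the
hypothesis boundary that the transformed proportions are constant in the
scale and the regression degenerates (the fitted $d - c$ tends to 0,
i.e. $p \to 0.5$, which is the wrong answer by construction); such trees
are reported as $p = 1$ (all wins) or $p = 0$ (all losses) directly.
With a single scale the fit reduces to the naive bootstrap proportion.

**BIC posteriors.** `bic_posteriors()` computes
$P(T_i) \propto \exp(\ln L_i - \text{pen}_i/2)$ through a max-shifted
softmax. Fully resolved candidates under a common model share the same
parameter count, so penalties cancel; they are exposed as a parameter
regardless.

## Bayes factors from MCMC traces

MCMC sampling itself is out of scope; the package consumes
log-likelihood traces (tab-separated, header row, one sample per row,
as written by common Bayesian phylogenetics programs), applies burn-in
and thinning, and pools chains.

The marginal likelihood is estimated by the harmonic mean of the
sampled likelihoods, computed entirely in log space:
$\widehat{\ln m} = -(\mathrm{logsumexp}(-\ln L) - \ln n)$. This
estimator is upwardly biased and high-variance — the test suite asserts
the bias direction on a conjugate normal model with a known marginal —
but it is cheap, requires nothing beyond the trace, and its
stabilisation is monitored by the *moving* version:
at cycle $i$ (1-based over the post-burn-in, post-thinning sample
sequence) the estimate uses the most recent
$\lceil 0.33\,i \rceil$ samples, advancing one cycle at a time. The
ceiling (with minimum window 1) makes the first cycle well defined; the
"current cycle" is deliberately the index within the retained sample
sequence, not the raw generation number, since burn-in samples carry no
information about the posterior. The final series value is the reported
point estimate.

`bayes_factor()` defaults to the log-of-absolute-difference
transformation $BF_{10} = \mathrm{sign}(\Delta)\cdot 2\ln|\Delta|$ with
$\Delta = \widehat{\ln m}_1 - \widehat{\ln m}_0$, which reproduces
published values of that form; the conventional $2\Delta$ is available
via `formula = "standard"`. Because sign conventions for such
transformed Bayes factors are notoriously inconsistent across sources,
the result always carries an explicit `direction` label derived from
the sign of $\Delta$ itself, plus a Jeffreys-style evidence category on
the magnitude: none ($|BF| < 2$), some ($2$–$6$), strong ($6$–$10$),
very strong ($\ge 10$). A zero difference yields $BF = 0$ with a
warning rather than an error.

## Supermatrix statistics

`concatenate_loci()` unions taxa across loci and fills absent blocks
with `"?"` (distinguishing locus absence from alignment gaps `"-"`,
though both are fully ambiguous to the likelihood).
`taxon_occupancy()` counts, per locus, taxa with at least
`min_residues` unambiguous residues; published occupancy figures rarely
state their presence criterion, so it is a parameter (default 1
residue). `matrix_summary()` reports per-locus lengths/occupancy and
*both* per-locus and per-taxon residue totals, because published
"residues per alignment" ranges are ambiguous between the two readings.

## Bait design

The bait-design stage reproduces the filtering pipeline used to build
target-capture probe sets, downstream of external RepeatMasker
(soft-masking) and BLAST (hit tables): N-runs of ≤ 10 bp are replaced
by T-runs (case-preserved, so masking survives), shorter sequences are
right-padded with T to the 120-bp bait length, and candidates are tiled
every 50 bp (≈ 2.4× nominal density). Hits are kept only when strictly
longer than 45 bp and strictly more than 75% identical; a candidate is
retained when it has at most 10 hits with melting temperature in
[62.5, 65] °C and at most 2 above 65 °C. Candidates containing residual
Ns are rejected as ambiguous; soft-masked fractions above 0.25 are
rejected as masked (the source protocol soft-masks but never states the
downstream rule, so the threshold is configurable).

Two pieces are deliberately pluggable because the source procedure
under-specifies them: the Tm model (default: salt-adjusted GC/length
approximation
$T_m = 81.5 + 16.6\log_{10}[\mathrm{Na}^+] + 0.41\,\%GC - 600/L -
1.0\,(100 - \%\mathrm{id})$ °C with $[\mathrm{Na}^+] = 0.9$ M; any `tm`
column already present in a hit table takes precedence) and the
"flanking region" criterion, whose published statement is ambiguous —
it is exposed as a predicate hook defaulting to pass-through rather
than silently guessed. Every rejected candidate carries exactly one
primary rejection reason, in the fixed precedence ambiguous → masked →
mid-bin → high-bin → flanking, and the pipeline is deterministic:
identical inputs give a byte-identical decision table.

## The synthetic-data module

The generators emulate the statistical structure each stage consumes:

* `simulate_alignment()` — forward CTMC simulation along a tree (root
  states from $\pi$, per-site gamma categories); site-pattern
  frequencies are tested against pruning-likelihood predictions by a
  chi-square test, tying the simulator and the engine to each other
  through an exact distributional identity.
* `simulate_missingness()` — per-locus occupancy drawn uniformly from a
  target range (default study-like: 5–36 of 44 taxa), taxa masked to
  `"?"`.
* `simulate_trace()` — stationary AR(1) log-likelihood traces
  ($x_i = \mu + \rho(x_{i-1} - \mu) + \varepsilon_i$, marginal
  $\mathcal{N}(\mu, \sigma^2)$), emulating well-mixed post-burn-in
  chains.
* `simulate_site_lnl()` — per-site log-likelihoods with controlled
  per-tree offsets and site noise, clipped at 0 to keep the
  discrete-data invariant $\ln L \le 0$ (a modelling convenience).
* `make_bait_fixture()` — a deterministic toy FASTA + hit table placing
  a case on each side of every bait-design threshold, with a
  hand-enumerated expectation table.

One run-level seed fans out to per-generator child seeds through
`derive_seed(seed, label)`, a 32-bit-safe polynomial label hash, so
modules reproduce in isolation and jointly; all generators restore the
session RNG state.

What passing tests do and do not show: the simulators produce
i.i.d.-across-sites data under the exact inference model, AR(1) traces,
and normal site-likelihood effects. Real supermatrices violate all
three (alignment error, model misspecification such as site-specific
profiles, heterotachy, non-normal and correlated site contributions),
so green tests certify the *procedures* — not that the procedures are
robust to misspecification on real data.

## Problem sizes and reference values

The suite exercises: exhaustive-enumeration agreement on 4-taxon trees
(binary and 4-state alphabets, 10 random branch-length draws per
topology, agreement to $10^{-10}$); branch-length recovery at 5,000
sites and $\alpha$/branch recovery at 10,000 sites (within 15%
relative); AU null uniformity over 200 zero-effect datasets of 200
sites (Kolmogorov–Smirnov); and full-pipeline topology recovery on an
8-taxon LG+G alignment of 2,000 sites against two wrong topologies
(true-tree BIC posterior > 0.95, wrong trees rejected by AU at 0.05).
These sizes were chosen as the smallest at which the asymptotic
behaviour each test asserts is comfortably established.

Arithmetic reproduction of the published four-tree comparison works
from the printed log-likelihoods: the likelihood-ratio column and the
small BIC posteriors reproduce at printed precision, and the
equal-penalty softmax of the two near-tied trees gives 0.285/0.715
against the printed 0.282/0.718 — the printed posteriors evidently come
from unrounded log-likelihoods, since no pair of values consistent with
the printed two-decimal table can yield 0.718 exactly.

## Known limitations

* Fully resolved input topologies only; semi-constrained searches that
  rearrange unconstrained nodes require a tree-search backend and are
  out of scope.
* No CAT-style site-specific profile models; MCMC output under such
  models is consumed as traces only.
* The harmonic-mean estimator's bias/variance pathologies are inherited
  by design (it is the estimator being reproduced); stepping-stone or
  thermodynamic-integration estimators are not provided.
* NEXUS, BAM/VCF and alignment estimation are out of scope; FASTA,
  relaxed PHYLIP, Newick, partition maps, site-lnL TSV and tabular
  traces are the supported formats.
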