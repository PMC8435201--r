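# Supermatrix construction and occupancy statistics.
#
# Per-locus alignments are concatenated over the union of their taxa;
# blocks where a taxon lacks a locus are filled with the fully ambiguous
# "?" symbol, which distinguishes locus absence from within-alignment
# gaps ("-") while both behave identically in the likelihood.

#' Concatenate per-locus alignments into a supermatrix
#'
#' @param loci named list of [alignment] objects over a common alphabet;
#'   names become locus names (unnamed input gets `locus1..locusN`).
#' @param fill symbol used for taxa absent from a locus (default `"?"`).
#' @return list with elements `alignment` (the supermatrix, taxa in
#'   first-appearance order) and `partition_map` (one entry per input
#'   locus, in input order).
#' @export
concatenate_loci <- function(loci, fill = "?") {
  if (length(loci) == 0L) value_error("need at least one locus")
  if (is.null(names(loci)) || any(!nzchar(names(loci))))
    names(loci) <- paste0("locus", seq_along(loci))
  if (anyDuplicated(names(loci)))
    value_error("duplicate locus names: %s",
                paste(unique(names(loci)[duplicated(names(loci))]), collapse = ", "))
  abs <- lapply(loci, function(a) attr(a, "alphabet"))
  ab <- abs[[1]]
  same <- vapply(abs, function(x) identical(x$states, ab$states), TRUE)
  if (!all(same)) value_error("loci use mixed alphabets")
  if (!fill %in% ab$missing)
    value_error("fill symbol '%s' is not a missing symbol of the alphabet", fill)
  taxa <- unique(unlist(lapply(loci, rownames)))
  lens <- vapply(loci, ncol, 0L)
  total <- sum(lens)
  out <- matrix(fill, nrow = length(taxa), ncol = total,
                dimnames = list(taxa, NULL))
  at <- 0L
  for (a in loci) {
    out[rownames(a), at + seq_len(ncol(a))] <- unclass(a)
    at <- at + ncol(a)
  }
  ends <- cumsum(lens)
  pm <- partition_map(names(loci), c(1L, utils::head(ends, -1L) + 1L), ends,
                      n_sites = total)
  list(alignment = alignment(out, ab), partition_map = pm)
}

#' Per-locus taxon occupancy
#'
#' Counts, for each locus of a partitioned supermatrix, the taxa that have
#' at least `min_residues` unambiguous (non-gap, non-missing) symbols
#' within the locus's columns.  The presence criterion is exposed as a
#' parameter because published occupancy figures rarely state one.
#'
#' @param aln concatenated [alignment].
#' @param pm matching [partition_map].
#' @param min_residues minimum unambiguous residues for presence
#'   (default 1).
#' @return named integer vector, one count per locus.
#' @export
taxon_occupancy <- function(aln, pm, min_residues = 1L) {
  if (min_residues < 1L) value_error("min_residues must be >= 1")
  if (pm$end[nrow(pm)] != ncol(aln))
    partition_error("partition map does not cover the alignment")
  miss <- is_missing_symbol(aln)
  counts <- vapply(seq_len(nrow(pm)), function(i) {
    cols <- partition_columns(pm, i)
    sum(rowSums(!miss[, cols, drop = FALSE]) >= min_residues)
  }, 0L)
  names(counts) <- pm$locus
  counts
}

#' Summary statistics of a per-locus alignment set
#'
#' Computes the per-locus table (aligned length, taxa present, total
#' unambiguous residues) and global summaries: locus-length range/mean,
#' occupancy range/mean, per-taxon residue totals and completeness.  Both
#' per-locus and per-taxon residue totals are reported because published
#' "residues per alignment" ranges are ambiguous between the two readings.
#'
#' @param loci named list of [alignment] objects (as [concatenate_loci()]).
#' @param min_residues presence criterion passed to occupancy counting.
#' @return object of class `matrix_summary`: list with `per_locus`
#'   (data frame), `per_taxon` (data frame with residue totals and
#'   completeness fractions) and `global` (named list).
#' @export
matrix_summary <- function(loci, min_residues = 1L) {
  cc <- concatenate_loci(loci)
  aln <- cc$alignment; pm <- cc$partition_map
  miss <- is_missing_symbol(aln)
  occ <- taxon_occupancy(aln, pm, min_residues)
  per_locus <- data.frame(
    locus = pm$locus,
    length = pm$end - pm$start + 1L,
    taxa_present = as.integer(occ),
    residues = vapply(seq_len(nrow(pm)), function(i)
      sum(!miss[, partition_columns(pm, i), drop = FALSE]), 0L),
    stringsAsFactors = FALSE)
  taxon_res <- rowSums(!miss)
  per_taxon <- data.frame(
    taxon = rownames(aln),
    residues = as.integer(taxon_res),
    completeness = taxon_res / ncol(aln),
    stringsAsFactors = FALSE)
  stopifnot(sum(per_locus$length) == ncol(aln))
  global <- list(
    n_loci = nrow(pm), n_taxa = nrow(aln), total_columns = ncol(aln),
    locus_length = c(min = min(per_locus$length), max = max(per_locus$length),
                     mean = mean(per_locus$length)),
    occupancy = c(min = min(per_locus$taxa_present),
                  max = max(per_locus$taxa_present),
                  mean = mean(per_locus$taxa_present)),
    residues_per_locus = c(min = min(per_locus$residues),
                           max = max(per_locus$residues),
                           mean = mean(per_locus$residues)),
    residues_per_taxon = c(min = min(per_taxon$residues),
                           max = max(per_taxon$residues),
                           mean = mean(per_taxon$residues)))
  structure(list(per_locus = per_locus, per_taxon = per_taxon,
                 global = global),
            class = "matrix_summary")
}

#' @export
print.matrix_summary <- function(x, ...) {
  g <- x$global
  cat(sprintf("supermatrix: %d loci, %d taxa, %d columns\n",
              g$n_loci, g$n_taxa, g$total_columns))
  cat(sprintf("locus length: %d-%d (mean %.1f)\n",
              g$locus_length["min"], g$locus_length["max"], g$locus_length["mean"]))
  cat(sprintf("occupancy:    %d-%d taxa (mean %.1f)\n",
              g$occupancy["min"], g$occupancy["max"], g$occupancy["mean"]))
  invisible(x)
}
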