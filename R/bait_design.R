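# Hybridization-capture bait design: sequence cleaning (short N-run
# replacement, T-padding), fixed-length tiling, hit-table filtering and
# the melting-temperature specificity filter.  BLAST/RepeatMasker run
# upstream; this module consumes their outputs (soft-masked FASTA and a
# tabular hit list).

#' Bait-design configuration
#'
#' All thresholds of the pipeline in one place.  Defaults: 120-bp baits
#' tiled every 50 bp (~2.4x nominal density), N-runs of up to 10 replaced
#' by T, hits kept only when strictly longer than 45 bp and strictly more
#' than 75% identical, specificity limits of at most 10 hits with Tm in
#' [62.5, 65] degC and at most 2 hits above 65 degC, and rejection of
#' candidates with more than 25% soft-masked (lowercase) positions.
#'
#' @param bait_length bait length in bp.
#' @param spacing distance between starts of neighbouring baits.
#' @param max_n_run longest ambiguous (N) run replaced by T repeats.
#' @param pad_to short sequences are right-padded with T to this length.
#' @param min_hit_length,min_identity strict lower bounds for keeping a
#'   hit (exclusive).
#' @param tm_mid_low,tm_mid_high bounds of the moderate-specificity Tm
#'   bin (inclusive).
#' @param max_mid_hits,max_high_hits maximum allowed hits in the mid bin
#'   and above `tm_mid_high`.
#' @param max_masked_fraction maximum tolerated soft-masked fraction.
#' @param tm_params parameters of the default Tm model (see
#'   [estimate_tm()]).
#' @param flanking_predicate optional `function(bait_id, hits)` returning
#'   `TRUE` to retain; stands in for the flanking-region criterion, whose
#'   published statement is ambiguous.  Default `NULL` = pass-through.
#' @export
bait_config <- function(bait_length = 120L, spacing = 50L, max_n_run = 10L,
                        pad_to = bait_length, min_hit_length = 45,
                        min_identity = 75, tm_mid_low = 62.5,
                        tm_mid_high = 65, max_mid_hits = 10L,
                        max_high_hits = 2L, max_masked_fraction = 0.25,
                        tm_params = list(na_molar = 0.9,
                                         mismatch_penalty = 1.0),
                        flanking_predicate = NULL) {
  as.list(environment())
}

#' Read a (possibly soft-masked) nucleotide FASTA
#'
#' Unlike [read_fasta_alignment()], sequences may have unequal lengths
#' and lower-case (soft-masked) letters are preserved.
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_masked_fasta <- function(path) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) format_error("empty FASTA file: %s", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) format_error("FASTA must start with a '>' header: %s", path)
  labels <- trimws(sub("^>", "", lines[hdr]))
  if (anyDuplicated(labels)) format_error("duplicate FASTA labels")
  seqs <- vapply(split(lines[!hdr], cumsum(hdr)[!hdr]), paste, "", collapse = "")
  seqs <- gsub("[[:space:]]", "", seqs)
  names(seqs) <- labels
  seqs
}

#' Clean a nucleotide sequence for bait tiling
#'
#' Every maximal run of ambiguous bases (N/n) of length `<= max_n_run`
#' is replaced by a thymine run of equal length (case preserved, so
#' soft-masking survives); longer N-runs are left intact and will reject
#' any bait tiled across them.  Sequences shorter than `pad_to` are
#' right-padded with `T`.
#'
#' @param seq a single nucleotide sequence string.
#' @param max_n_run longest N-run to replace.
#' @param pad_to minimum output length.
#' @return cleaned sequence; idempotent.
#' @export
clean_sequence <- function(seq, max_n_run = 10L, pad_to = 120L) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    value_error("seq must be a single non-empty string")
  chars <- strsplit(seq, "")[[1]]
  runs <- rle(chars %in% c("N", "n"))
  pos <- cumsum(c(1L, runs$lengths))
  for (i in seq_along(runs$lengths)) {
    if (runs$values[i] && runs$lengths[i] <= max_n_run) {
      idx <- pos[i]:(pos[i] + runs$lengths[i] - 1L)
      chars[idx] <- ifelse(chars[idx] == "n", "t", "T")
    }
  }
  out <- paste(chars, collapse = "")
  if (nchar(out) < pad_to)
    out <- paste0(out, strrep("T", pad_to - nchar(out)))
  out
}

#' Tile bait candidates across a cleaned sequence
#'
#' Candidates start at 0, `spacing`, `2*spacing`, ... while
#' `start + bait_length <= length`.  Candidates containing any remaining
#' ambiguous base are flagged `rejected:ambiguous`; otherwise candidates
#' whose soft-masked (lowercase) fraction exceeds `max_masked_fraction`
#' are flagged `rejected:masked`; the rest are `candidate`.
#'
#' @param seq cleaned sequence (see [clean_sequence()]).
#' @param source_id label of the source sequence.
#' @param bait_length,spacing,max_masked_fraction see [bait_config()].
#' @return data frame: bait_id, source_id, start (0-based), length,
#'   sequence, masked_fraction, status.
#' @export
tile_baits <- function(seq, source_id = "seq", bait_length = 120L,
                       spacing = 50L, max_masked_fraction = 0.25) {
  L <- nchar(seq)
  if (L < bait_length)
    value_error("sequence shorter (%d) than bait length (%d); clean/pad first",
                L, bait_length)
  starts <- seq.int(0L, L - bait_length, by = spacing)
  subs <- substring(seq, starts + 1L, starts + bait_length)
  masked <- vapply(strsplit(subs, ""), function(ch)
    sum(ch %in% letters) / length(ch), 0)
  has_n <- grepl("[Nn]", subs)
  status <- rep("candidate", length(starts))
  status[masked > max_masked_fraction] <- "rejected:masked"
  status[has_n] <- "rejected:ambiguous"
  data.frame(
    bait_id = sprintf("%s_b%d", source_id, seq_along(starts)),
    source_id = source_id, start = starts, length = bait_length,
    sequence = subs, masked_fraction = masked, status = status,
    stringsAsFactors = FALSE)
}

#' Filter a hit table by alignment length and identity
#'
#' Strict inequalities: a hit is retained iff `length > min_length` and
#' `identity > min_identity` (so a 45-bp or 75%-identity hit is dropped).
#'
#' @param hits data frame with at least `length` and `identity` columns.
#' @param min_length,min_identity exclusive lower bounds.
#' @export
filter_hits <- function(hits, min_length = 45, min_identity = 75) {
  hits[hits$length > min_length & hits$identity > min_identity, ,
       drop = FALSE]
}

#' Estimate a hybridization melting temperature for a hit
#'
#' Salt-adjusted GC/length approximation with a per-percent-mismatch
#' penalty:
#' `Tm = 81.5 + 16.6*log10([Na+]) + 0.41*GC% - 600/length -
#'  penalty*(100 - identity)`.
#' The model and its parameters are configurable; any `tm` column already
#' present in a hit table takes precedence in the pipeline.
#'
#' @param length alignment length in bp (> 0).
#' @param identity percent identity in `[0, 100]`.
#' @param gc_percent GC content of the matched span in percent.
#' @param params list with `na_molar` and `mismatch_penalty`.
#' @return melting temperature in degrees Celsius.
#' @export
estimate_tm <- function(length, identity, gc_percent = 50,
                        params = list(na_molar = 0.9, mismatch_penalty = 1.0)) {
  if (any(length <= 0)) value_error("hit length must be > 0")
  81.5 + 16.6 * log10(params$na_molar) + 0.41 * gc_percent -
    600 / length - params$mismatch_penalty * (100 - identity)
}

#' Specificity filter for one bait candidate
#'
#' Retains the candidate iff the number of its (already length/identity
#' filtered) hits with Tm in `[tm_mid_low, tm_mid_high]` is at most
#' `max_mid_hits`, the number with Tm above `tm_mid_high` is at most
#' `max_high_hits`, and the optional flanking predicate passes.
#'
#' @param bait_id candidate id (for the flanking predicate).
#' @param tm numeric vector of hit melting temperatures (possibly empty).
#' @param config a [bait_config()].
#' @return list with `retained` (logical) and `status`
#'   (`"retained"` or `"rejected:mid-bin"` / `"rejected:high-bin"` /
#'   `"rejected:flanking"`).
#' @export
specificity_filter <- function(bait_id, tm, config = bait_config()) {
  n_mid <- sum(tm >= config$tm_mid_low & tm <= config$tm_mid_high)
  n_high <- sum(tm > config$tm_mid_high)
  if (n_mid > config$max_mid_hits)
    return(list(retained = FALSE, status = "rejected:mid-bin"))
  if (n_high > config$max_high_hits)
    return(list(retained = FALSE, status = "rejected:high-bin"))
  if (!is.null(config$flanking_predicate) &&
      !isTRUE(config$flanking_predicate(bait_id, tm)))
    return(list(retained = FALSE, status = "rejected:flanking"))
  list(retained = TRUE, status = "retained")
}

#' Run the full bait-design pipeline
#'
#' Cleans every source sequence, tiles candidates, then for each
#' still-viable candidate filters its hits by length/identity, estimates
#' missing melting temperatures, and applies the Tm specificity filter.
#' The pipeline is deterministic: identical inputs and configuration give
#' a byte-identical decision table.
#'
#' @param seqs named character vector of (possibly soft-masked)
#'   nucleotide sequences, or a FASTA path.
#' @param hits data frame with columns `bait_id`, `target_id`, `length`,
#'   `identity` and optionally `tm` and `gc_percent`; or a TSV path.
#'   `NULL` means no hits (all viable candidates retained).
#' @param config a [bait_config()].
#' @return the candidate table of [tile_baits()] for all sources, with
#'   final `status` for every candidate (retained + rejected = all).
#' @export
design_baits <- function(seqs, hits = NULL, config = bait_config()) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- read_masked_fasta(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    value_error("sequences must be named")
  if (is.character(hits) && length(hits) == 1L) {
    hits <- utils::read.table(hits, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  }
  cleaned <- vapply(seqs, clean_sequence, "",
                    max_n_run = config$max_n_run, pad_to = config$pad_to)
  cand <- do.call(rbind, lapply(names(cleaned), function(id)
    tile_baits(cleaned[[id]], id, config$bait_length, config$spacing,
               config$max_masked_fraction)))
  for (i in which(cand$status == "candidate")) {
    h <- if (is.null(hits)) NULL else
      hits[hits$bait_id == cand$bait_id[i], , drop = FALSE]
    if (is.null(h) || nrow(h) == 0L) {
      cand$status[i] <- "retained"
      next
    }
    h <- filter_hits(h, config$min_hit_length, config$min_identity)
    tm <- if (nrow(h) == 0L) numeric(0)
    else if ("tm" %in% names(h) && !anyNA(h$tm)) h$tm
    else estimate_tm(h$length, h$identity,
                     if ("gc_percent" %in% names(h)) h$gc_percent else 50,
                     config$tm_params)
    cand$status[i] <- specificity_filter(cand$bait_id[i], tm, config)$status
  }
  rownames(cand) <- NULL
  cand
}

#' Write retained baits to FASTA
#'
#' @param decisions output of [design_baits()].
#' @param path output FASTA path.
#' @export
write_bait_fasta <- function(decisions, path) {
  keep <- decisions[decisions$status == "retained", , drop = FALSE]
  writeLines(as.vector(rbind(paste0(">", keep$bait_id),
                             toupper(keep$sequence))), path)
  invisible(path)
}
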