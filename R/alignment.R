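# Alignment container and sequence readers/writers.
#
# An alignment is a taxa x sites character matrix over a declared alphabet.
# Amino-acid data treat "X", "?" and "-" as fully ambiguous (partial
# likelihood 1 for every state); nucleotide data treat "N", "?" and "-" the
# same way.  Gblocks-trimmed supermatrices mix all three, so no distinction
# is drawn between gap and missing in the likelihood machinery.

AA_SYMBOLS  <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
DNA_SYMBOLS <- c("A", "C", "G", "T")

#' @keywords internal
alphabet_spec <- function(alphabet, symbols = NULL) {
  if (inherits(alphabet, "tt_alphabet")) return(alphabet)
  if (identical(alphabet, "aa")) {
    states <- AA_SYMBOLS; missing <- c("X", "?", "-")
  } else if (identical(alphabet, "dna")) {
    states <- DNA_SYMBOLS; missing <- c("N", "?", "-")
  } else if (identical(alphabet, "generic")) {
    if (is.null(symbols)) value_error("generic alphabet requires explicit symbols")
    states <- toupper(symbols); missing <- c("?", "-")
  } else {
    value_error("unknown alphabet '%s' (use \"aa\", \"dna\" or \"generic\")",
                as.character(alphabet)[1])
  }
  structure(list(name = if (is.character(alphabet)) alphabet else "generic",
                 states = states, missing = missing),
            class = "tt_alphabet")
}

#' Construct a validated multiple sequence alignment
#'
#' @param seqs named character vector of sequences (one string per taxon) or
#'   a taxa x sites character matrix with row names.
#' @param alphabet `"aa"`, `"dna"`, `"generic"`, or an alphabet object.
#' @param symbols state symbols when `alphabet = "generic"`.
#' @return an object of class `alignment`: a character matrix (taxa in rows,
#'   upper-cased symbols) with attributes `alphabet` and `n_sites`.
#' @export
alignment <- function(seqs, alphabet = "aa", symbols = NULL) {
  ab <- alphabet_spec(alphabet, symbols)
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      format_error("all sequences must carry non-empty taxon labels")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L)
      alignment_error("ragged alignment: sequence lengths %s",
                      paste(unique(lens), collapse = ", "))
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    if (is.null(mat)) format_error("empty alignment")
    rownames(mat) <- names(seqs)
  }
  if (nrow(mat) == 0L) format_error("empty alignment")
  if (is.null(rownames(mat)) || any(!nzchar(rownames(mat))))
    format_error("all taxa must carry non-empty labels")
  if (anyDuplicated(rownames(mat)))
    format_error("duplicate taxon labels: %s",
                 paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  ok <- mat %in% c(ab$states, ab$missing)
  if (!all(ok)) {
    bad <- unique(mat[!ok])
    format_error("symbols not in %s alphabet: %s", ab$name,
                 paste(bad, collapse = ", "))
  }
  structure(mat, alphabet = ab, n_sites = ncol(mat), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  ab <- attr(x, "alphabet")
  cat(sprintf("alignment: %d taxa x %d sites (%s alphabet)\n",
              nrow(x), ncol(x), ab$name))
  invisible(x)
}

#' @keywords internal
aln_taxa <- function(aln) rownames(aln)

#' @keywords internal
is_missing_symbol <- function(aln) {
  ab <- attr(aln, "alphabet")
  matrix(unclass(aln) %in% ab$missing, nrow = nrow(aln),
         dimnames = dimnames(aln))
}

#' Read a FASTA alignment
#'
#' Sequences must be of equal length (an alignment, not a collection);
#' symbols are upper-cased and validated against the declared alphabet.
#'
#' @inheritParams alignment
#' @param path FASTA file path.
#' @return an [alignment] with taxa in file order.
#' @export
read_fasta_alignment <- function(path, alphabet = "aa", symbols = NULL) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) format_error("empty FASTA file: %s", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) format_error("FASTA must start with a '>' header: %s", path)
  idx <- cumsum(hdr)
  labels <- trimws(sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, "", collapse = "")
  if (length(seqs) != length(labels))
    format_error("FASTA record without sequence lines: %s", path)
  seqs <- gsub("[[:space:]]", "", seqs)
  names(seqs) <- labels
  alignment(seqs, alphabet, symbols)
}

#' Write an alignment to FASTA
#'
#' @param aln an [alignment].
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @export
write_fasta_alignment <- function(aln, path, width = 80L) {
  out <- character(0)
  for (i in seq_len(nrow(aln))) {
    s <- paste(aln[i, ], collapse = "")
    chunks <- substring(s, seq(1, nchar(s), width),
                        pmin(seq(1, nchar(s), width) + width - 1L, nchar(s)))
    out <- c(out, paste0(">", rownames(aln)[i]), chunks)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a relaxed PHYLIP alignment
#'
#' Relaxed sequential PHYLIP: a header line `n_taxa n_sites`, then one
#' `name sequence` record per taxon (whitespace-separated, any label
#' length, sequence possibly continued on following lines).
#'
#' @inheritParams read_fasta_alignment
#' @export
read_phylip_alignment <- function(path, alphabet = "aa", symbols = NULL) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) format_error("PHYLIP file too short: %s", path)
  hd <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]))
  if (length(hd) != 2L || anyNA(hd))
    format_error("PHYLIP header must be 'n_taxa n_sites': %s", path)
  body <- lines[-1]
  labels <- character(0); seqs <- character(0); cur <- 0L
  for (ln in body) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (cur > 0L && nchar(seqs[cur]) < hd[2] && length(parts) == 1L) {
      seqs[cur] <- paste0(seqs[cur], parts[1])  # continuation line
    } else {
      if (length(parts) < 2L) format_error("malformed PHYLIP record: '%s'", ln)
      cur <- cur + 1L
      labels[cur] <- parts[1]
      seqs[cur] <- paste(parts[-1], collapse = "")
    }
  }
  if (length(labels) != hd[1])
    format_error("PHYLIP header declares %d taxa, found %d", hd[1], length(labels))
  if (any(nchar(seqs) != hd[2]))
    alignment_error("PHYLIP header declares %d sites, records disagree", hd[2])
  names(seqs) <- labels
  alignment(seqs, alphabet, symbols)
}
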