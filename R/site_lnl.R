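# Per-site log-likelihood matrices: the substrate of the RELL bootstrap,
# AU test and BIC posteriors.  Rows are candidate trees, columns sites.

#' Construct a validated per-site log-likelihood matrix
#'
#' @param values numeric trees x sites matrix (natural logs; `-Inf`
#'   allowed for zero-probability sites, `NaN`/`NA` rejected).
#' @param tree_ids row labels; taken from `rownames(values)` if absent.
#' @param check_nonpositive assert `values <= 0`, the invariant for
#'   log-likelihoods of discrete-state data (default `TRUE`).
#' @return a numeric matrix of class `site_lnl_matrix` with tree ids as
#'   row names.
#' @export
site_lnl_matrix <- function(values, tree_ids = rownames(values),
                            check_nonpositive = TRUE) {
  values <- as.matrix(values)
  if (is.null(tree_ids)) tree_ids <- paste0("tree", seq_len(nrow(values)))
  if (length(tree_ids) != nrow(values))
    value_error("tree_ids length does not match row count")
  if (anyDuplicated(tree_ids)) value_error("duplicate tree ids")
  if (anyNA(values)) format_error("non-numeric or missing site log-likelihood")
  if (any(is.nan(values))) format_error("NaN site log-likelihood")
  if (check_nonpositive && any(values > 0))
    value_error("positive site log-likelihood for discrete-state data")
  storage.mode(values) <- "double"
  rownames(values) <- as.character(tree_ids)
  structure(values, class = c("site_lnl_matrix", class(matrix())))
}

#' Read a per-site log-likelihood matrix
#'
#' Two dialects are accepted:
#' * the package's TSV: one row per tree, first column the tree id,
#'   remaining columns per-site natural-log likelihoods;
#' * the common ML-program per-site lnL layout: a header line
#'   `n_trees n_sites`, then one `tree_id v1 v2 ...` whitespace-separated
#'   row per tree.
#'
#' @param path file path.
#' @param check_nonpositive see [site_lnl_matrix()].
#' @export
read_site_lnl_matrix <- function(path, check_nonpositive = TRUE) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) format_error("empty site-lnL file: %s", path)
  first <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  ml_dialect <- length(first) == 2L &&
    !anyNA(suppressWarnings(as.integer(first)))
  if (ml_dialect) lines <- lines[-1]
  rows <- strsplit(trimws(lines), "[[:space:]]+")
  widths <- lengths(rows)
  if (length(unique(widths)) > 1L)
    format_error("ragged rows in site-lnL file (widths %s)",
                 paste(unique(widths), collapse = ", "))
  if (widths[1] < 2L) format_error("site-lnL rows need a tree id and >=1 site")
  ids <- vapply(rows, `[`, "", 1L)
  vals <- suppressWarnings(
    t(vapply(rows, function(r) as.numeric(r[-1]), numeric(widths[1] - 1L))))
  if (widths[1] == 2L) vals <- matrix(vals, ncol = 1L)  # vapply drops dims
  if (anyNA(vals)) format_error("non-numeric cell in site-lnL file")
  if (ml_dialect) {
    hd <- as.integer(first)
    if (nrow(vals) != hd[1] || ncol(vals) != hd[2])
      format_error("site-lnL header declares %dx%d, found %dx%d",
                   hd[1], hd[2], nrow(vals), ncol(vals))
  }
  site_lnl_matrix(vals, ids, check_nonpositive = check_nonpositive)
}

#' Write a per-site log-likelihood matrix as TSV
#'
#' Values are written with 17 significant digits so that a read/write
#' round trip reproduces every double bit-for-bit.
#'
#' @param m a [site_lnl_matrix()] (or plain matrix with row names).
#' @param path output path.
#' @export
write_site_lnl_matrix <- function(m, path) {
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("tree", seq_len(nrow(m)))
  lines <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(ids[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
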