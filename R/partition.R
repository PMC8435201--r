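# Partition maps: per-locus column ranges of a concatenated alignment.
#
# On disk the format is the common ML-program convention of 1-based
# inclusive ranges, one "name = start-end" line per locus.  Internally the
# same 1-based inclusive coordinates are kept in a validated data frame;
# column-slicing helpers do the off-by-one bookkeeping in one place.

#' Construct a validated partition map
#'
#' @param locus character vector of unique locus names.
#' @param start,end 1-based inclusive column ranges, contiguous and
#'   non-overlapping in order.
#' @param n_sites if supplied, the entries must cover `1..n_sites` exactly.
#' @return a `partition_map` data frame with columns locus/start/end.
#' @export
partition_map <- function(locus, start, end, n_sites = NULL) {
  if (length(locus) == 0L) partition_error("empty partition map")
  if (anyDuplicated(locus))
    partition_error("duplicate locus names: %s",
                    paste(unique(locus[duplicated(locus)]), collapse = ", "))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) partition_error("partition with start > end")
  if (start[1] != 1L) partition_error("first partition must start at column 1")
  if (length(start) > 1L) {
    gaps <- start[-1] != end[-length(end)] + 1L
    if (any(gaps))
      partition_error("gap or overlap at column %d",
                      end[which(gaps)[1]] + 1L)
  }
  if (!is.null(n_sites) && end[length(end)] != n_sites)
    partition_error("partitions end at %d but alignment has %d sites",
                    end[length(end)], n_sites)
  structure(data.frame(locus = as.character(locus), start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("partition_map", "data.frame"))
}

#' Read a partition map file
#'
#' Lines of `name = start-end` (1-based inclusive); blank lines and `#`
#' comments are ignored.  Entries must tile `1..n_sites` contiguously.
#'
#' @param path file path.
#' @param n_sites number of columns of the alignment the map describes.
#' @export
read_partition_map <- function(path, n_sites) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) partition_error("empty partition file: %s", path)
  m <- regmatches(lines, regexec("^(.*?)[[:space:]]*=[[:space:]]*([0-9]+)[[:space:]]*-[[:space:]]*([0-9]+)$", lines))
  bad <- lengths(m) != 4L
  if (any(bad))
    format_error("malformed partition line: '%s'", lines[bad][1])
  locus <- vapply(m, `[`, "", 2L)
  start <- as.integer(vapply(m, `[`, "", 3L))
  end <- as.integer(vapply(m, `[`, "", 4L))
  if (any(end > n_sites))
    partition_error("partition end %d exceeds alignment length %d",
                    max(end), n_sites)
  partition_map(locus, start, end, n_sites = n_sites)
}

#' Write a partition map file
#' @param pm a [partition_map].
#' @param path output path.
#' @export
write_partition_map <- function(pm, path) {
  writeLines(sprintf("%s = %d-%d", pm$locus, pm$start, pm$end), path)
  invisible(path)
}

#' @keywords internal
partition_columns <- function(pm, i) seq.int(pm$start[i], pm$end[i])
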