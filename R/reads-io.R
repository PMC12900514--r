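#' Read tables of CRAC-like reads
#'
#' Reads are stored as a header-bearing TSV with columns `start`, `end`,
#' `strand`, `umi`, `replicate`, `condition`. Coordinates are 1-based
#' inclusive on the rDNA unit. Malformed rows (non-integer coordinates,
#' `start > end`, `start < 1`, bad strand) are rejected with their line
#' numbers (line 1 is the header).
#'
#' @param path file path.
#' @return data.frame of read records in file order.
#' @export
read_reads <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                          stringsAsFactors = FALSE, comment.char = "", quote = "")
  required <- c("start", "end", "strand", "umi", "replicate", "condition")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("reads table is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[required]
  start <- suppressWarnings(as.integer(df$start))
  end <- suppressWarnings(as.integer(df$end))
  line <- seq_len(nrow(df)) + 1L
  bad <- is.na(start) | is.na(end) | start < 1L | start > end |
    !(df$strand %in% c("+", "-"))
  if (any(bad))
    stop("malformed read record at line(s): ",
         paste(utils::head(line[bad], 5L), collapse = ", "))
  df$start <- start
  df$end <- end
  validate_reads(df)
}

#' @rdname read_reads
#' @param records data.frame of read records (see [read_reads()] for columns).
#' @export
write_reads <- function(records, path) {
  records <- validate_reads(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# shared invariants for in-memory read tables
validate_reads <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("start", "end", "strand", "umi", "replicate", "condition")
  missing <- setdiff(required, names(records))
  if (length(missing))
    stop("read records missing column(s): ", paste(missing, collapse = ", "))
  records <- as.data.frame(records)[required]
  if (nrow(records)) {
    if (any(records$start < 1L) || any(records$start > records$end))
      stop("read records must satisfy 1 <= start <= end")
    if (!all(records$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    nch <- unique(nchar(records$umi))
    if (length(nch) > 1L)
      stop("UMI length must be constant within a read set")
  }
  rownames(records) <- NULL
  records
}

#' Write a coverage profile as bedGraph
#'
#' Converts the internal 1-based inclusive per-base track to the bedGraph
#' dialect (0-based half-open intervals), merging runs of adjacent equal
#' values into single intervals. The exported value is the profile's
#' normalized frequency (`freq`, hits per million) by default.
#'
#' @param profile a [coverage_profile()].
#' @param path output path.
#' @param value which per-base vector to export, `"freq"` or `"counts"`.
#' @param seqname reference name used in the track.
#' @param drop_zero drop zero-valued intervals (`TRUE`, the default) or emit
#'   them; an all-zero profile with `drop_zero = TRUE` yields an empty track.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path, value = c("freq", "counts"),
                           seqname = "rDNA", drop_zero = TRUE) {
  stopifnot(inherits(profile, "coverage_profile"))
  value <- match.arg(value)
  v <- profile[[value]]
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- if (drop_zero) r$values != 0 else rep(TRUE, length(r$values))
  gr <- GenomicRanges::GRanges(
    rep(seqname, sum(keep)),
    IRanges::IRanges(start = starts[keep], end = ends[keep]),
    score = r$values[keep]
  )
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' Read a bedGraph file as a per-base value vector
#'
#' Inverse of [write_bedgraph()] up to the coordinate-convention conversion:
#' intervals are expanded back to a per-base vector of length `unit_length`,
#' with positions not covered by any interval set to 0.
#'
#' @param path bedGraph file.
#' @param unit_length length of the unit in nt.
#' @return numeric vector of per-base values, length `unit_length`.
#' @export
read_bedgraph <- function(path, unit_length) {
  unit_length <- as.integer(unit_length)
  gr <- rtracklayer::import(path, format = "bedGraph")
  v <- numeric(unit_length)
  if (length(gr)) {
    s <- GenomicRanges::start(gr)
    e <- GenomicRanges::end(gr)
    if (any(s < 1L) || any(e > unit_length))
      stop("bedGraph intervals fall outside [1, ", unit_length, "]")
    for (i in seq_along(gr)) v[s[i]:e[i]] <- gr$score[i]
  }
  v
}

#' Read / write per-base coverage as plain TSV
#'
#' Columns `pos`, `count`, `freq`; one row per position of the unit.
#'
#' @param profile a [coverage_profile()].
#' @param path file path.
#' @return `write_coverage_tsv()` returns `path` invisibly;
#'   `read_coverage_tsv()` returns a [coverage_profile()].
#' @export
write_coverage_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "coverage_profile"))
  utils::write.table(
    data.frame(pos = seq_along(profile$counts), count = profile$counts,
               freq = profile$freq),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage_tsv
#' @param condition,replicate labels attached to the profile read back.
#' @export
read_coverage_tsv <- function(path, condition = NA_character_,
                              replicate = NA_character_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("pos", "count") %in% names(df)),
            identical(as.integer(df$pos), seq_len(nrow(df))))
  new_coverage_profile(as.integer(df$count), condition, replicate)
}
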