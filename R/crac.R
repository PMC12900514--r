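#' Remove PCR duplicates
#'
#' Collapses read records sharing the same `(start, end, strand, umi)` key
#' to a single record — the first in input order. Reads with identical
#' coordinates but distinct UMIs are biological duplicates and are all
#' retained; strand is part of the key as a conservative choice (a no-op on
#' sense-only data).
#'
#' @param records data.frame of read records from one replicate of one
#'   condition.
#' @return list with `records` (the unique records, input order preserved)
#'   and `n_removed`.
#' @examples
#' r <- data.frame(start = 1L, end = 30L, strand = "+", umi = "ACGTA",
#'                 replicate = "rep1", condition = "wt")
#' dedup(r[c(1, 1, 1), ])$n_removed
#' @export
dedup <- function(records) {
  records <- validate_reads(records)
  dup <- duplicated(records[c("start", "end", "strand", "umi")])
  out <- records[!dup, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, n_removed = sum(dup))
}

row_extreme <- function(m, fun) {
  do.call(fun, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

new_coverage_profile <- function(counts, condition = NA_character_,
                                 replicate = NA_character_) {
  counts <- as.integer(counts)
  total <- sum(counts)
  freq <- if (total > 0) counts / total * 1e6 else numeric(length(counts))
  structure(list(counts = counts, total = total, freq = freq,
                 condition = condition, replicate = replicate),
            class = "coverage_profile")
}

#' Per-base 3'-end coverage
#'
#' Tallies, for each position of the unit, the number of reads whose 3' end
#' falls there: `end` for sense reads, `start` (the leftmost coordinate) for
#' antisense reads. The default policy counts sense reads only, since Pol I
#' transcribes the unit sense-strand. Frequencies are normalized to hits
#' per million of the reads counted.
#'
#' @param records deduplicated read records.
#' @param unit_length length of the unit in nt.
#' @param strand_policy `"sense"` (default) to count `+` reads only, or
#'   `"both"` to also tally `-` reads at their 3' ends.
#' @param condition,replicate labels stored on the profile (defaulting to
#'   the unique label in `records` if there is one).
#' @return an object of class `coverage_profile`: list with per-position
#'   `counts`, `total`, per-position `freq` (hits per million) and labels.
#' @export
coverage_3p <- function(records, unit_length,
                        strand_policy = c("sense", "both"),
                        condition = NULL, replicate = NULL) {
  records <- validate_reads(records)
  strand_policy <- match.arg(strand_policy)
  unit_length <- as.integer(unit_length)
  if (nrow(records) && any(records$end > unit_length))
    stop("read coordinates outside [1, ", unit_length, "]")
  single_label <- function(x) if (length(unique(x)) == 1L) x[1L] else NA_character_
  if (is.null(condition)) condition <- single_label(records$condition)
  if (is.null(replicate)) replicate <- single_label(records$replicate)
  plus <- records$strand == "+"
  ends <- records$end[plus]
  if (strand_policy == "both")
    ends <- c(ends, records$start[!plus])
  new_coverage_profile(tabulate(ends, nbins = unit_length),
                       condition, replicate)
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile:", length(x$counts), "nt, total", x$total, "reads")
  if (!is.na(x$condition)) cat(" [", x$condition, "/", x$replicate, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Aggregate replicate coverage profiles
#'
#' Pointwise mean, min and max of the normalized frequencies of one
#' condition's replicates — the mean profile and min-max envelope drawn in
#' replicate occupancy figures.
#'
#' @param profiles list of [coverage_3p()] profiles of equal length and a
#'   single condition.
#' @return an object of class `replicate_aggregate`: list with `condition`,
#'   `n_replicates` and per-position `mean`, `min`, `max`.
#' @export
aggregate_replicates <- function(profiles) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "coverage_profile")))
  lens <- vapply(profiles, function(p) length(p$freq), integer(1))
  if (length(unique(lens)) != 1L) stop("profiles have mismatched lengths")
  conds <- unique(vapply(profiles, function(p) p$condition, character(1)))
  if (length(conds) > 1L)
    stop("profiles mix conditions: ", paste(conds, collapse = ", "))
  m <- vapply(profiles, function(p) p$freq, numeric(lens[1L]))
  m <- matrix(m, nrow = lens[1L])
  structure(list(
    condition = conds,
    n_replicates = length(profiles),
    mean = rowMeans(m),
    min = row_extreme(m, pmin),
    max = row_extreme(m, pmax)
  ), class = "replicate_aggregate")
}

#' One-call read-processing pipeline for a condition
#'
#' Splits a read table by condition and replicate, removes PCR duplicates
#' within each replicate, computes 3'-end coverage and returns the per-
#' replicate profiles. This is the dedup -> coverage step of the occupancy
#' pipeline; see [aggregate_replicates()] for the envelope step.
#'
#' @param reads read records for one or more conditions.
#' @param unit_length length of the unit in nt.
#' @param strand_policy passed to [coverage_3p()].
#' @return named list (by condition) of lists of `coverage_profile`s, in
#'   replicate order.
#' @export
process_reads <- function(reads, unit_length,
                          strand_policy = c("sense", "both")) {
  reads <- validate_reads(reads)
  strand_policy <- match.arg(strand_policy)
  out <- list()
  for (cond in unique(reads$condition)) {
    rc <- reads[reads$condition == cond, , drop = FALSE]
    reps <- unique(rc$replicate)
    out[[cond]] <- lapply(reps, function(r) {
      rr <- dedup(rc[rc$replicate == r, , drop = FALSE])$records
      coverage_3p(rr, unit_length, strand_policy)
    })
  }
  out
}
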