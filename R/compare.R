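#' Conservative envelope difference between two conditions
#'
#' At each position, the smallest difference compatible with the two
#' replicate min-max envelopes: positive `minA - maxB` where condition A's
#' envelope lies wholly above B's, negative `-(minB - maxA)` where B's lies
#' wholly above A's, and 0 wherever the envelopes overlap. Being computed
#' from the closest envelope points, `|d|` never exceeds the difference of
#' the mean profiles.
#'
#' @param agg_a,agg_b [aggregate_replicates()] results of equal length;
#'   positive values mean A above B.
#' @return numeric vector `d` of signed differences (frequency units).
#' @export
envelope_difference <- function(agg_a, agg_b) {
  stopifnot(inherits(agg_a, "replicate_aggregate"),
            inherits(agg_b, "replicate_aggregate"))
  if (length(agg_a$mean) != length(agg_b$mean))
    stop("aggregates have mismatched lengths")
  d <- numeric(length(agg_a$mean))
  above <- agg_a$min > agg_b$max
  below <- agg_b$min > agg_a$max
  d[above] <- agg_a$min[above] - agg_b$max[above]
  d[below] <- -(agg_b$min[below] - agg_a$max[below])
  d
}

#' Low-coverage-masked log2 ratio of two mean profiles
#'
#' `r(x) = log2(meanA(x) / meanB(x))` at positions passing the coverage
#' rule; a position is masked when the minimum raw (deduplicated) count at
#' that position over all replicates of both conditions falls below
#' `c_min`. Positions where a mean frequency is still zero off-mask are
#' force-masked with a warning rather than emitting infinities.
#'
#' @param agg_a,agg_b [aggregate_replicates()] results (A is the ratio
#'   numerator).
#' @param counts_a,counts_b lists of the per-replicate raw-count profiles
#'   ([coverage_3p()] results, or bare count vectors) behind each aggregate.
#' @param c_min minimum per-replicate raw count required to keep a position
#'   (default 5).
#' @return list with `ratio` (log2 ratio, `NA` where masked) and `mask`
#'   (logical, `TRUE` = excluded).
#' @export
log2_ratio <- function(agg_a, agg_b, counts_a, counts_b, c_min = 5) {
  stopifnot(inherits(agg_a, "replicate_aggregate"),
            inherits(agg_b, "replicate_aggregate"))
  L <- length(agg_a$mean)
  if (length(agg_b$mean) != L) stop("aggregates have mismatched lengths")
  as_counts <- function(x) {
    m <- vapply(x, function(p) {
      if (inherits(p, "coverage_profile")) as.numeric(p$counts) else as.numeric(p)
    }, numeric(L))
    matrix(m, nrow = L)
  }
  cm <- cbind(as_counts(counts_a), as_counts(counts_b))
  mask <- apply(cm, 1L, min) < c_min
  ratio <- rep(NA_real_, L)
  zero <- !mask & (agg_a$mean == 0 | agg_b$mean == 0)
  if (any(zero)) {
    warning("force-masking ", sum(zero), " zero-frequency position(s)")
    mask[zero] <- TRUE
  }
  ratio[!mask] <- log2(agg_a$mean[!mask] / agg_b$mean[!mask])
  list(ratio = ratio, mask = mask)
}

star_label <- function(p) {
  ifelse(p < 0.005, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Per-region summed frequencies with two-sample tests
#'
#' Sums each replicate's normalized frequency (hits per million) over every
#' annotated region, reports per-condition mean and SD, and compares the
#' conditions region by region with a Welch two-sided two-sample t-test.
#' Significance stars follow the 0.05 / 0.01 / 0.005 convention. With fewer
#' than two replicates in either condition the sums are reported and the
#' test columns are `NA`.
#'
#' @param profiles_a,profiles_b lists of [coverage_3p()] profiles (the
#'   replicates of conditions A and B).
#' @param annotation an [rdna_annotation()] matching the profile length.
#' @return data.frame with one row per region: per-condition means and SDs,
#'   the per-replicate sums (as list columns `sums_a`, `sums_b`), the ratio
#'   of means `ratio_ab`, `t`, `p` and `stars`.
#' @export
region_stats <- function(profiles_a, profiles_b, annotation) {
  stopifnot(inherits(annotation, "rdna_annotation"))
  L <- unit_length(annotation)
  region_sums <- function(profiles) {
    vapply(profiles, function(p) {
      stopifnot(length(p$freq) == L)
      vapply(seq_len(nrow(annotation)), function(i)
        sum(p$freq[annotation$start[i]:annotation$end[i]]), numeric(1))
    }, numeric(nrow(annotation)))
  }
  sa <- matrix(region_sums(profiles_a), nrow = nrow(annotation))
  sb <- matrix(region_sums(profiles_b), nrow = nrow(annotation))
  out <- data.frame(
    region = annotation$name,
    mean_a = rowMeans(sa), sd_a = apply(sa, 1L, stats::sd),
    mean_b = rowMeans(sb), sd_b = apply(sb, 1L, stats::sd),
    stringsAsFactors = FALSE
  )
  out$ratio_ab <- out$mean_a / out$mean_b
  tt <- lapply(seq_len(nrow(out)), function(i)
    welch_or_degenerate(sa[i, ], sb[i, ]))
  out$t <- vapply(tt, `[`, numeric(1), 1L)
  out$p <- vapply(tt, `[`, numeric(1), 2L)
  out$stars <- ifelse(is.na(out$p), NA_character_, star_label(out$p))
  out$sums_a <- lapply(seq_len(nrow(out)), function(i) as.vector(sa[i, ]))
  out$sums_b <- lapply(seq_len(nrow(out)), function(i) as.vector(sb[i, ]))
  out
}

#' Cumulative occupancy distribution of a condition
#'
#' Running sum of the mean frequency profile normalized to end at 1, with
#' the per-replicate CDFs giving a min-max envelope. A condition whose
#' polymerases clear the 5' end more efficiently has its CDF shifted
#' rightward (lower at every position).
#'
#' @param profiles list of [coverage_3p()] profiles (replicates of one
#'   condition), each with nonzero total.
#' @return object of class `cdf_profile`: list with `mean` (the CDF of the
#'   mean profile), `min`, `max` (pointwise envelope over replicate CDFs),
#'   `median_position` (first position where the mean CDF reaches 0.5) and
#'   `condition`.
#' @export
cdf_profile <- function(profiles) {
  if (inherits(profiles, "coverage_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L)
  cdf1 <- function(p) {
    if (sum(p$freq) == 0) stop("cannot form a CDF from an all-zero profile")
    cumsum(p$freq) / sum(p$freq)
  }
  cds <- vapply(profiles, cdf1, numeric(length(profiles[[1L]]$freq)))
  cds <- matrix(cds, nrow = length(profiles[[1L]]$freq))
  mean_freq <- rowMeans(vapply(profiles, function(p) p$freq,
                               numeric(nrow(cds))))
  cmean <- cumsum(mean_freq) / sum(mean_freq)
  structure(list(
    mean = cmean,
    min = row_extreme(cds, pmin),
    max = row_extreme(cds, pmax),
    median_position = which(cmean >= 0.5)[1L],
    condition = profiles[[1L]]$condition
  ), class = "cdf_profile")
}

#' Shift metrics between two cumulative occupancy distributions
#'
#' `delta_median` is the difference of the first positions at which the two
#' mean CDFs reach 0.5 (A minus B; ties broken toward smaller positions).
#' `signed_area` is the mean of `C_A(x) - C_B(x)` over the unit: positive
#' when A accumulates more 5'-proximally than B, i.e. when B's CDF sits at
#' or right of A's.
#'
#' @param cdf_a,cdf_b [cdf_profile()] results of equal length.
#' @return list with `delta_median` and `signed_area`.
#' @export
cdf_shift <- function(cdf_a, cdf_b) {
  stopifnot(inherits(cdf_a, "cdf_profile"), inherits(cdf_b, "cdf_profile"))
  L <- length(cdf_a$mean)
  if (length(cdf_b$mean) != L) stop("CDFs have mismatched lengths")
  list(
    delta_median = cdf_a$median_position - cdf_b$median_position,
    signed_area = sum(cdf_a$mean - cdf_b$mean) / L
  )
}
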