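#' Normalize probe intensities to the 5S control
#'
#' Slot-blot intensities are made comparable across replicates by dividing
#' each probe's intensity by the mean of the two 5S control probes of the
#' same replicate (the Pol III 5S signal is the loading/labelling control).
#'
#' @param table quantification table: data.frame with columns `condition`,
#'   `replicate`, `probe`, `intensity` (nonnegative).
#' @param catalog a [probe_catalog()] identifying the two `control_5S`
#'   probes.
#' @return data.frame with columns `condition`, `replicate`, `probe`,
#'   `ratio` for every non-control probe.
#' @export
normalize_to_5s <- function(table, catalog = default_probe_catalog()) {
  stopifnot(is.data.frame(table),
            all(c("condition", "replicate", "probe", "intensity") %in% names(table)),
            inherits(catalog, "probe_catalog"))
  if (any(table$intensity < 0)) stop("intensities must be nonnegative")
  controls <- catalog$name[catalog$role == "control_5S"]
  key <- interaction(table$condition, table$replicate, drop = TRUE)
  out <- lapply(levels(key), function(k) {
    sub <- table[key == k, , drop = FALSE]
    ctl <- sub$intensity[match(controls, sub$probe)]
    if (any(is.na(ctl)))
      stop("missing 5S control probe(s) in ", sub$condition[1L], "/",
           sub$replicate[1L], ": ",
           paste(controls[is.na(ctl)], collapse = ", "))
    denom <- mean(ctl)
    if (denom == 0)
      stop("zero 5S denominator in ", sub$condition[1L], "/", sub$replicate[1L])
    keep <- !(sub$probe %in% controls)
    data.frame(condition = sub$condition[keep], replicate = sub$replicate[keep],
               probe = sub$probe[keep], ratio = sub$intensity[keep] / denom,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Composite Pol I signal
#'
#' The per-replicate arithmetic mean over a set of member probes' 5S
#' ratios, as used to summarize overall Pol I transcriptional output from
#' several region probes. Members that are themselves groups of probes
#' (e.g. the three 5'ETS probes contributing a single 5'ETS value) are
#' averaged first.
#'
#' @param ratios output of [normalize_to_5s()].
#' @param members list of members; each element is a character vector of
#'   probe names that is averaged into one member value. Default: the three
#'   5'ETS probes (as one member), 18S.2, 25S.1 and 3'ETS.
#' @return data.frame with columns `condition`, `replicate`, `ratio`
#'   (the composite value).
#' @export
composite_poli_signal <- function(ratios,
                                  members = list(
                                    c("5'ETS-1", "5'ETS-2", "5'ETS-3"),
                                    "18S.2", "25S.1", "3'ETS")) {
  stopifnot(is.data.frame(ratios), length(members) >= 1L)
  key <- interaction(ratios$condition, ratios$replicate, drop = TRUE)
  out <- lapply(levels(key), function(k) {
    sub <- ratios[key == k, , drop = FALSE]
    vals <- vapply(members, function(m) {
      v <- sub$ratio[match(m, sub$probe)]
      if (any(is.na(v)))
        stop("missing member probe(s): ",
             paste(m[is.na(v)], collapse = ", "))
      mean(v)
    }, numeric(1))
    data.frame(condition = sub$condition[1L], replicate = sub$replicate[1L],
               ratio = mean(vals), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Calibrated lane trace
#'
#' A densitometry trace of one gel lane, calibrated to molecular size:
#' pairs of (size in nt, intensity). Sizes must be strictly monotone; the
#' trace is stored in increasing size order.
#'
#' @param size sizes in nt.
#' @param intensity nonnegative intensities.
#' @return object of class `lane_profile`.
#' @export
lane_profile <- function(size, intensity) {
  stopifnot(length(size) == length(intensity), length(size) >= 2L,
            all(intensity >= 0))
  o <- order(size)
  size <- as.numeric(size[o]); intensity <- as.numeric(intensity[o])
  if (any(diff(size) <= 0)) stop("sizes must be strictly monotone")
  structure(list(size = size, intensity = intensity), class = "lane_profile")
}

#' Integrate a lane trace over a size window
#'
#' Trapezoidal integral of the calibrated intensity trace over
#' `[window[1], window[2]]` nt, with the trace linearly interpolated at the
#' window edges. The default window, 70-90 nt, brackets the abortive
#' transcript species released by 5'ETS pausing.
#'
#' @param lane a [lane_profile()].
#' @param window numeric `c(lo, hi)` size window in nt, inside the trace
#'   range.
#' @return the integrated intensity (intensity units x nt).
#' @export
window_quant <- function(lane, window = c(70, 90)) {
  stopifnot(inherits(lane, "lane_profile"), length(window) == 2L)
  lo <- window[1L]; hi <- window[2L]
  if (lo >= hi) stop("window must satisfy lo < hi")
  if (lo < lane$size[1L] || hi > lane$size[length(lane$size)])
    stop("window [", lo, ", ", hi, "] outside trace range [",
         lane$size[1L], ", ", lane$size[length(lane$size)], "]")
  inner <- lane$size > lo & lane$size < hi
  xs <- c(lo, lane$size[inner], hi)
  ys <- c(stats::approx(lane$size, lane$intensity, lo)$y,
          lane$intensity[inner],
          stats::approx(lane$size, lane$intensity, hi)$y)
  sum(diff(xs) * (utils::head(ys, -1L) + utils::tail(ys, -1L)) / 2)
}

#' Fold changes versus a reference condition, with tests
#'
#' For each probe (or band), divides each condition's mean 5S ratio by the
#' reference condition's mean ratio and tests per-replicate ratios against
#' the reference with a Welch two-sided t-test. The reference row has fold
#' change 1 by construction. Stars follow 0.05 / 0.01 / 0.005.
#'
#' @param ratios output of [normalize_to_5s()] (or any data.frame with
#'   columns `condition`, `replicate`, `probe`, `ratio`; a missing `probe`
#'   column, e.g. from [composite_poli_signal()], is treated as one band).
#' @param reference reference condition label.
#' @return data.frame with one row per (probe, condition): `mean`, `sd`,
#'   `fold_change`, `t`, `p`, `stars`.
#' @export
fold_change_stats <- function(ratios, reference) {
  stopifnot(is.data.frame(ratios),
            all(c("condition", "replicate", "ratio") %in% names(ratios)))
  if (!"probe" %in% names(ratios)) ratios$probe <- "band"
  if (!reference %in% ratios$condition)
    stop("reference condition absent: ", reference)
  out <- list()
  for (pb in unique(ratios$probe)) {
    sub <- ratios[ratios$probe == pb, , drop = FALSE]
    ref <- sub$ratio[sub$condition == reference]
    for (cond in unique(sub$condition)) {
      v <- sub$ratio[sub$condition == cond]
      tp <- welch_or_degenerate(v, ref)
      out[[length(out) + 1L]] <- data.frame(
        probe = pb, condition = cond,
        mean = mean(v), sd = stats::sd(v),
        fold_change = mean(v) / mean(ref),
        t = tp[1L], p = tp[2L],
        stars = if (is.na(tp[2L])) NA_character_ else star_label(tp[2L]),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

welch_or_degenerate <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) return(c(NA_real_, NA_real_))
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) return(c(0, 1))
    return(c(Inf, 0))
  }
  w <- stats::t.test(x, y, var.equal = FALSE)
  c(unname(w$statistic), w$p.value)
}
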