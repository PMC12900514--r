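#' Simulation configuration
#'
#' Bundles the knobs of the CRAC-like read simulator. `read_length` is either
#' a single fixed length or a `c(min, max)` range sampled uniformly per read;
#' `pcr_duplication` is the mean number of extra PCR copies per unique
#' cross-linking event (extra copies are Geometric-distributed and share the
#' original coordinates and UMI exactly).
#'
#' @param n_molecules simulated molecules per replicate (the occupancy
#'   snapshot the reads sample).
#' @param n_replicates replicates per condition; default 3, matching
#'   triplicate profiling experiments.
#' @param n_events cross-linking events (unique reads before PCR
#'   duplication) sampled per replicate.
#' @param read_length fixed read length in nt, or a `c(min, max)` range.
#' @param pcr_duplication mean extra PCR copies per unique event (`>= 0`).
#' @param umi_length UMI length in nt (default 5, the random-barcode length
#'   of the sequencing adapter).
#' @param seed optional integer seed; a fixed seed makes simulator output
#'   reproducible byte-for-byte.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_molecules = 20000L, n_replicates = 3L,
                              n_events = 50000L, read_length = 30L,
                              pcr_duplication = 1, umi_length = 5L,
                              seed = NULL) {
  stopifnot(n_molecules >= 1, n_replicates >= 1, n_events >= 1,
            length(read_length) %in% 1:2, all(read_length >= 1),
            pcr_duplication >= 0, umi_length >= 1)
  if (length(read_length) == 2L && read_length[1] > read_length[2])
    stop("read_length range must be increasing")
  structure(list(
    n_molecules = as.integer(n_molecules),
    n_replicates = as.integer(n_replicates),
    n_events = as.integer(n_events),
    read_length = as.integer(read_length),
    pcr_duplication = pcr_duplication,
    umi_length = as.integer(umi_length),
    seed = seed
  ), class = "simulation_config")
}

#' Configuration used for the packaged preset experiments
#'
#' Same defaults as [simulation_config()] but with read lengths drawn
#' uniformly from 20-50 nt, reflecting the length variability that nuclease
#' trimming produces and giving hotspot positions enough (start, UMI) key
#' diversity that PCR-duplicate removal does not saturate.
#'
#' @param ... overrides passed to [simulation_config()].
#' @return a `simulation_config`.
#' @export
preset_config <- function(...) {
  simulation_config(read_length = c(20L, 50L), ...)
}

#' Simulate single-molecule elongation outcomes
#'
#' Each molecule enters at site 1 and walks along the unit; at site `x` it
#' dwells an Exponential(mean `tau[x]`) time and terminates there with
#' probability `p(x)`, otherwise steps forward. The walk is sampled exactly
#' via its closed-form outcome distribution (termination at `x` with
#' probability `S(x) p(x)`, full-length with probability `S(L+1)`), and the
#' per-site dwell totals across reached visits are drawn as Gamma sums of
#' the per-visit Exponential dwells — distributionally identical to the
#' explicit walk but linear in `L` rather than in `n * L`.
#'
#' @param model a [pause_termination_model()].
#' @param n_molecules number of molecules.
#' @param seed optional integer seed.
#' @return an object of class `molecule_outcomes`: list with `term_site`
#'   (per-molecule termination site, `NA` for full-length molecules),
#'   `n_molecules`, `n_full_length`, and per-site aggregates `n_reached`,
#'   `n_terminated` and `dwell_total` (summed dwell of all visits at each
#'   site, the quantity a cross-linking snapshot samples).
#' @export
simulate_molecules <- function(model, n_molecules = 20000L, seed = NULL) {
  stopifnot(inherits(model, "pause_termination_model"), n_molecules >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_molecules <- as.integer(n_molecules)
  L <- model$L
  ss <- steady_state(model)
  # outcome L+1 codes a full-length molecule
  outcome <- sample.int(L + 1L, n_molecules, replace = TRUE,
                        prob = c(ss$A, ss$full_length_rate) / model$alpha)
  term_site <- ifelse(outcome > L, NA_integer_, outcome)
  n_terminated <- tabulate(term_site[!is.na(term_site)], nbins = L)
  # reached x  <=>  not terminated before x
  n_reached <- n_molecules - c(0L, cumsum(n_terminated))[seq_len(L)]
  dwell_total <- numeric(L)
  pos <- n_reached > 0L
  dwell_total[pos] <- stats::rgamma(sum(pos), shape = n_reached[pos],
                                    scale = model$tau[pos])
  structure(list(
    term_site = as.integer(term_site),
    n_molecules = n_molecules,
    n_full_length = sum(is.na(term_site)),
    n_reached = n_reached,
    n_terminated = n_terminated,
    dwell_total = dwell_total,
    L = L
  ), class = "molecule_outcomes")
}

random_umis <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = len)
  do.call(paste0, as.data.frame(t(m), stringsAsFactors = FALSE))
}

#' Emit CRAC-like reads from simulated molecules
#'
#' Cross-linking captures polymerases in proportion to residence time, so
#' each read's 3' end is sampled with probability proportional to the total
#' simulated dwell at that site (expected coverage proportional to the
#' steady-state occupancy `O(x)`). Reads are sense-strand with
#' `end = x`, `start = max(1, x - readlen + 1)` and a random UMI; each
#' unique event then receives Geometric-distributed extra PCR copies that
#' share its coordinates and UMI.
#'
#' @param outcomes a [simulate_molecules()] result.
#' @param config a [simulation_config()].
#' @param replicate,condition labels stamped on the emitted records.
#' @param seed optional integer seed.
#' @return data.frame of read records (see [read_reads()] for columns).
#' @export
emit_crac_reads <- function(outcomes, config = simulation_config(),
                            replicate = "rep1", condition = "cond",
                            seed = NULL) {
  stopifnot(inherits(outcomes, "molecule_outcomes"),
            inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  L <- outcomes$L
  if (all(outcomes$dwell_total == 0)) stop("no dwell mass to sample reads from")
  n <- config$n_events
  ends <- sample.int(L, n, replace = TRUE, prob = outcomes$dwell_total)
  rl <- if (length(config$read_length) == 1L) {
    rep(config$read_length, n)
  } else {
    sample(seq.int(config$read_length[1], config$read_length[2]), n,
           replace = TRUE)
  }
  reads <- data.frame(
    start = pmax(1L, ends - rl + 1L),
    end = ends,
    strand = "+",
    umi = random_umis(n, config$umi_length),
    replicate = replicate,
    condition = condition,
    stringsAsFactors = FALSE
  )
  if (config$pcr_duplication > 0) {
    extra <- stats::rgeom(n, prob = 1 / (1 + config$pcr_duplication))
    reads <- reads[rep.int(seq_len(n), 1L + extra), , drop = FALSE]
    rownames(reads) <- NULL
  }
  reads
}

#' Abortive-transcript length spectrum
#'
#' The lengths of prematurely released transcripts are the termination
#' sites of the simulated molecules. Under the packaged presets the dominant
#' mode falls in the first 300 nt of the 5'ETS, where the strong pause
#' cluster sits.
#'
#' @param outcomes a [simulate_molecules()] result.
#' @return data.frame with columns `length` (nt) and `count`, one row per
#'   observed abortive length; attributes `n_full_length` and `n_molecules`
#'   carry the conservation bookkeeping (`sum(count) + n_full_length ==
#'   n_molecules`).
#' @export
emit_abortive_spectrum <- function(outcomes) {
  stopifnot(inherits(outcomes, "molecule_outcomes"))
  counts <- outcomes$n_terminated
  keep <- which(counts > 0L)
  structure(
    data.frame(length = keep, count = counts[keep]),
    n_full_length = outcomes$n_full_length,
    n_molecules = outcomes$n_molecules
  )
}

#' Simulated slot-blot probe intensities
#'
#' Emulates the densitometry readout of a nascent-transcript labelling
#' assay: each `polI_signal` probe reports the steady-state occupancy summed
#' over its target region, the two `control_5S` probes report a
#' condition-independent constant (the Pol III control), and the
#' `background_IGS2` probe reports near-zero background. Replicates receive
#' independent multiplicative lognormal noise with the given coefficient of
#' variation (mean 1, so intensities are unbiased).
#'
#' @param model a [pause_termination_model()] (or a [steady_state()]).
#' @param catalog a [probe_catalog()].
#' @param noise_cv coefficient of variation of the lognormal noise; 0 gives
#'   noise-free intensities.
#' @param n_replicates replicates to emit.
#' @param condition condition label.
#' @param annotation an [rdna_annotation()] matching the model length.
#' @param control_intensity constant intensity of each 5S control probe.
#' @param background_intensity constant IGS2 background intensity.
#' @param seed optional integer seed.
#' @return data.frame with columns `condition`, `replicate`, `probe`,
#'   `intensity` (a quantification table, see [normalize_to_5s()]).
#' @export
emit_probe_signals <- function(model, catalog = default_probe_catalog(),
                               noise_cv = 0.1, n_replicates = 3L,
                               condition = "cond",
                               annotation = default_annotation(),
                               control_intensity = 5000,
                               background_intensity = 0.5,
                               seed = NULL) {
  stopifnot(inherits(catalog, "probe_catalog"))
  if (!is.null(seed)) set.seed(seed)
  ss <- if (inherits(model, "steady_state")) model else steady_state(model)
  if (length(ss$O) != unit_length(annotation))
    stop("annotation unit_length does not match model length")
  expected <- vapply(seq_len(nrow(catalog)), function(i) {
    switch(catalog$role[i],
      polI_signal = {
        reg <- catalog$target_region[i]
        if (!reg %in% annotation$name)
          stop("unknown target region for probe ", catalog$name[i], ": ", reg)
        sum(ss$O[region_positions(annotation, reg)])
      },
      control_5S = control_intensity,
      background_IGS2 = background_intensity)
  }, numeric(1))
  n_probe <- nrow(catalog)
  out <- data.frame(
    condition = condition,
    replicate = rep(paste0("rep", seq_len(n_replicates)), each = n_probe),
    probe = rep(catalog$name, n_replicates),
    intensity = rep(expected, n_replicates),
    stringsAsFactors = FALSE
  )
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    out$intensity <- out$intensity *
      stats::rlnorm(nrow(out), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  out
}

#' Simulate a full multi-condition CRAC experiment
#'
#' Runs [simulate_molecules()] and [emit_crac_reads()] for every replicate
#' of every condition and binds the read records into one table, the same
#' shape a combined aligned-read export takes.
#'
#' @param models named list of [pause_termination_model()]s (or preset names
#'   accepted by [preset_model()]), one per condition.
#' @param config a [simulation_config()]; `config$seed` (if set) seeds the
#'   whole experiment.
#' @return data.frame of read records for all conditions and replicates.
#' @examples
#' cfg <- preset_config(n_molecules = 2000, n_events = 5000, seed = 1)
#' reads <- simulate_crac_experiment(list(wt = "wt", superpol = "superpol"),
#'                                   config = cfg)
#' table(reads$condition, reads$replicate)
#' @export
simulate_crac_experiment <- function(models, config = preset_config()) {
  stopifnot(is.list(models), length(names(models)) == length(models))
  if (!is.null(config$seed)) set.seed(config$seed)
  models <- lapply(models, function(m) {
    if (is.character(m)) preset_model(m) else m
  })
  out <- vector("list", length(models) * config$n_replicates)
  k <- 0L
  for (cond in names(models)) {
    for (r in seq_len(config$n_replicates)) {
      mol <- simulate_molecules(models[[cond]], config$n_molecules)
      k <- k + 1L
      out[[k]] <- emit_crac_reads(mol, config, replicate = paste0("rep", r),
                                  condition = cond)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
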