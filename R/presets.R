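# Packaged pause landscapes and condition presets.
#
# The default landscape places a cluster of strong pause elements in the
# first 300 nt of the 5'ETS and a weaker secondary cluster across the
# 5.8S/early-25S boundary, flat dwell elsewhere. Dwell times are in
# arbitrary units with baseline 1.

.polterm_defaults <- list(
  unit_length     = 6859L,
  tau_baseline    = 1,
  # 16 five-nt pause elements within the TSS..300 window (positions 24..298)
  ets_pause_starts = seq(24L, 294L, by = 18L),
  ets_pause_width  = 5L,
  ets_pause_tau    = 400,
  # 12 five-nt elements across the 5.8S/25S boundary
  mid_pause_starts = seq(2880L, 3320L, by = 40L),
  mid_pause_width  = 5L,
  mid_pause_tau    = 40,
  kappa_wt         = 5.1e-5,
  alpha            = 1,
  bmh21_kappa_fold = 8,
  # calibration targets for the SuperPol preset (see calibrate_superpol)
  target_ets_share_ratio   = 1.25,
  target_full_length_ratio = 1.5
)

expand_elements <- function(starts, width) {
  as.vector(outer(seq_len(width) - 1L, starts, "+"))
}

#' Positions of the packaged 5'ETS pause cluster
#'
#' The sites (within the first 300 nt of the 5'ETS) carrying elevated dwell
#' times in the packaged pause landscape. These are the sites targeted by
#' the `"wt_bmh21"` / `"superpol_bmh21"` presets.
#'
#' @return integer vector of 1-based positions.
#' @export
ets_pause_cluster <- function() {
  d <- .polterm_defaults
  expand_elements(d$ets_pause_starts, d$ets_pause_width)
}

default_tau <- function(ets_scale = 1) {
  d <- .polterm_defaults
  tau <- rep(d$tau_baseline, d$unit_length)
  tau[ets_pause_cluster()] <- d$ets_pause_tau * ets_scale
  tau[expand_elements(d$mid_pause_starts, d$mid_pause_width)] <- d$mid_pause_tau
  tau
}

# Solve the SuperPol parameters (5'ETS-cluster dwell scale s, hazard kappa)
# so that the closed form gives exactly:
#   * 5'ETS occupancy-share ratio WT/SuperPol = 1.25
#   * full-length rate ratio SuperPol/WT = 1.5
# mirroring the reduced pausing and increased rRNA output of the variant.
calibrate_superpol <- function() {
  d <- .polterm_defaults
  ann <- default_annotation()
  wt <- steady_state(pause_termination_model(default_tau(), d$kappa_wt, d$alpha))
  ets <- region_positions(ann, "5'ETS")
  share <- function(ss) sum(ss$O[ets]) / sum(ss$O)
  share_wt <- share(wt)
  target_F <- d$target_full_length_ratio * wt$full_length_rate
  kappa_for <- function(s) {
    stats::uniroot(function(k) {
      ss <- steady_state(pause_termination_model(default_tau(s), k, d$alpha))
      ss$full_length_rate - target_F
    }, c(1e-9, 5e-4), tol = 1e-14)$root
  }
  ratio_for <- function(s) {
    ss <- steady_state(pause_termination_model(default_tau(s), kappa_for(s), d$alpha))
    share_wt / share(ss)
  }
  s <- stats::uniroot(function(s) ratio_for(s) - d$target_ets_share_ratio,
                      c(0.1, 0.9), tol = 1e-12)$root
  list(ets_scale = s, kappa = kappa_for(s))
}

#' Packaged condition presets
#'
#' Returns the [pause_termination_model()] for one of four packaged
#' conditions on the default 6859-nt pause landscape:
#'
#' * `"wt"`: wild-type Pol I; strong pausing in the 5'ETS cluster, hazard
#'   `kappa = 5.1e-5` everywhere.
#' * `"superpol"`: reduced 5'ETS pausing and reduced hazard, calibrated at
#'   construction so that the closed-form 5'ETS occupancy-share ratio
#'   WT/SuperPol equals 1.25 and the full-length rate ratio
#'   SuperPol/WT equals 1.5 (a self-check recomputes both via
#'   [steady_state()] and aborts if they are off).
#' * `"wt_bmh21"` / `"superpol_bmh21"`: the corresponding untreated model
#'   with the termination hazard multiplied 8-fold at the 5'ETS pause
#'   cluster sites only, representing a drug that acts preferentially on
#'   long-paused elongation complexes.
#'
#' @param preset one of `"wt"`, `"superpol"`, `"wt_bmh21"`,
#'   `"superpol_bmh21"`.
#' @return a [pause_termination_model()].
#' @examples
#' wt <- preset_model("wt")
#' sp <- preset_model("superpol")
#' steady_state(sp)$full_length_rate / steady_state(wt)$full_length_rate
#' @export
preset_model <- function(preset = c("wt", "superpol", "wt_bmh21", "superpol_bmh21")) {
  preset <- match.arg(preset)
  d <- .polterm_defaults
  base <- sub("_bmh21$", "", preset)
  if (base == "wt") {
    tau <- default_tau()
    kappa <- rep(d$kappa_wt, d$unit_length)
  } else {
    cal <- superpol_calibration()
    tau <- default_tau(cal$ets_scale)
    kappa <- rep(cal$kappa, d$unit_length)
  }
  if (grepl("_bmh21$", preset)) {
    cl <- ets_pause_cluster()
    kappa[cl] <- kappa[cl] * d$bmh21_kappa_fold
  }
  model <- pause_termination_model(tau, kappa, d$alpha)
  if (preset == "superpol") check_superpol(model)
  model
}

# calibration cache: the solve is deterministic, run it once per session
.preset_cache <- new.env(parent = emptyenv())

superpol_calibration <- function() {
  if (is.null(.preset_cache$superpol))
    .preset_cache$superpol <- calibrate_superpol()
  .preset_cache$superpol
}

check_superpol <- function(model) {
  d <- .polterm_defaults
  ann <- default_annotation()
  wt <- steady_state(preset_model("wt"))
  sp <- steady_state(model)
  ets <- region_positions(ann, "5'ETS")
  share_ratio <- (sum(wt$O[ets]) / sum(wt$O)) / (sum(sp$O[ets]) / sum(sp$O))
  fl_ratio <- sp$full_length_rate / wt$full_length_rate
  if (abs(share_ratio - d$target_ets_share_ratio) > 1e-6 ||
      abs(fl_ratio - d$target_full_length_ratio) > 1e-6)
    stop("SuperPol preset self-check failed: share ratio ",
         format(share_ratio), ", full-length ratio ", format(fl_ratio))
  invisible(TRUE)
}
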