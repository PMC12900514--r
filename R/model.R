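#' Pause-coupled premature-termination model
#'
#' A single-molecule elongation model of RNA polymerase I on a unit of `L`
#' sites. At each site `x` the enzyme dwells for an Exponential time with
#' mean `tau[x]` (arbitrary time units) and is released prematurely with
#' probability `p(x) = 1 - exp(-kappa[x] * tau[x])`: the termination hazard
#' `kappa` acts throughout the dwell, so the longer the pause at a site, the
#' more likely the polymerase is to abort there. `kappa = 0` recovers
#' uninterrupted elongation. New molecules initiate at rate `alpha`.
#'
#' `kappa` may be a scalar (uniform hazard) or a per-site vector, which is
#' how drug treatments that act preferentially on paused complexes are
#' represented.
#'
#' @param tau per-site mean dwell times, all `> 0`; its length sets `L`.
#' @param kappa termination hazard per dwell-time unit, `>= 0`; scalar or
#'   length-`L` vector.
#' @param alpha initiation rate (events per time unit), `> 0`.
#' @return an object of class `pause_termination_model` with elements `L`,
#'   `tau`, `kappa` (length `L`), `alpha` and the derived per-visit
#'   termination probability `p`.
#' @examples
#' m <- pause_termination_model(tau = rep(1, 3), kappa = log(2))
#' steady_state(m)
#' @export
pause_termination_model <- function(tau, kappa = 0, alpha = 1) {
  tau <- as.numeric(tau)
  if (!length(tau) || any(!is.finite(tau)) || any(tau <= 0))
    stop("all dwell times tau must be positive and finite")
  L <- length(tau)
  kappa <- as.numeric(kappa)
  if (length(kappa) == 1L) kappa <- rep(kappa, L)
  if (length(kappa) != L) stop("kappa must be scalar or length L")
  if (any(kappa < 0)) stop("kappa must be nonnegative")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a positive scalar")
  p <- -expm1(-kappa * tau)
  structure(list(L = L, tau = tau, kappa = kappa, alpha = alpha, p = p),
            class = "pause_termination_model")
}

#' @export
print.pause_termination_model <- function(x, ...) {
  cat("pause_termination_model: L =", x$L,
      " alpha =", x$alpha,
      " kappa in [", format(min(x$kappa)), ",", format(max(x$kappa)), "]\n")
  cat("  tau range [", format(min(x$tau)), ",", format(max(x$tau)),
      "]; elevated (pause) sites:", sum(x$tau > min(x$tau)), "\n")
  invisible(x)
}

#' Closed-form steady state of the pause/termination model
#'
#' For a [pause_termination_model()] computes, per site `x`:
#' survival `S(x) = prod_{y<x} (1 - p(y))` (probability that an initiating
#' molecule reaches `x`), flux `J(x) = alpha * S(x)`, occupancy
#' `O(x) = J(x) * tau(x)` (expected residence; what a cross-linking snapshot
#' samples), abortive production `A(x) = J(x) * p(x)`, and the full-length
#' synthesis rate `F = alpha * S(L+1)`. Conservation `alpha = F + sum(A)`
#' holds identically.
#'
#' @param model a [pause_termination_model()].
#' @return an object of class `steady_state`: a list with `S` (length
#'   `L + 1`; `S[L+1]` is the survival past the last site), `J`, `O`, `A`
#'   (length `L`), and scalar `full_length_rate`.
#' @export
steady_state <- function(model) {
  stopifnot(inherits(model, "pause_termination_model"))
  L <- model$L
  S <- c(1, cumprod(1 - model$p))
  J <- model$alpha * S[seq_len(L)]
  structure(list(
    S = S,
    J = J,
    O = J * model$tau,
    A = J * model$p,
    full_length_rate = model$alpha * S[L + 1L],
    alpha = model$alpha
  ), class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("steady_state: L =", length(x$O),
      " full-length rate =", format(x$full_length_rate),
      "(", format(100 * x$full_length_rate / x$alpha), "% of initiation )\n")
  invisible(x)
}

#' Occupancy summed over an annotated region
#'
#' @param ss a [steady_state()].
#' @param annotation an [rdna_annotation()] whose unit length equals the
#'   model's `L`.
#' @param region region name.
#' @return total occupancy over the region's positions.
#' @export
region_occupancy <- function(ss, annotation, region) {
  stopifnot(inherits(ss, "steady_state"))
  if (unit_length(annotation) != length(ss$O))
    stop("annotation unit_length does not match model length")
  sum(ss$O[region_positions(annotation, region)])
}
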