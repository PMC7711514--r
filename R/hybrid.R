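#' Stationary entropy production of a run-and-tumble particle on a ring
#'
#' A diffusing particle on a ring whose drift switches between `v1` and
#' `v2` in a Poisson process (tumbling). The stationary joint density is
#' uniform, `1/(2L)` per mode, with mode currents \eqn{j_i = v_i/(2L)},
#' and the stationary entropy production is
#' \deqn{\dot S_i = \frac{v_1^2 + v_2^2}{2D} = -\dot S_e,}
#' independent of the tumbling rate and the ring size. Two-mode switching
#' with symmetric rates produces no entropy of its own (the log-ratio of
#' the switch propagators vanishes); for \eqn{|v_1| = |v_2| = v} the
#' drift-diffusion value \eqn{v^2/D} is recovered.
#'
#' @param v1,v2 drift in the two modes (length/time).
#' @param D diffusion constant (> 0).
#' @return stationary \eqn{\dot S_i} in nats/time (`se` is minus this).
#' @export
rtp_stationary_entropy <- function(v1, v2, D) {
  if (D <= 0) stop("diffusion constant must be positive")
  (v1^2 + v2^2) / (2 * D)
}

#' Switching-diffusion specification
#'
#' Diffusion on a ring with `M` drift modes `v[i]` and a mode-transition
#' rate matrix `alpha` (`alpha[i, j]` = rate of switching from mode `i`
#' to mode `j`). Run-and-tumble is the special case `M = 2` with
#' symmetric rates.
#'
#' @param v numeric vector of mode drifts (length `M >= 2`).
#' @param D diffusion constant (> 0).
#' @param L ring circumference (> 0).
#' @param alpha `M x M` matrix of switching rates (off-diagonal >= 0;
#'   diagonal is refilled), or a single rate for symmetric two-mode
#'   switching.
#' @return object of class `"switching_spec"` with the validated `alpha`
#'   as a [rate_matrix()] and the stationary mode weights `z`.
#' @export
switching_spec <- function(v, D, L, alpha) {
  M <- length(v)
  if (M < 2L) stop("need at least two drift modes")
  stopifnot(D > 0, L > 0)
  if (length(alpha) == 1L) {
    if (M != 2L) stop("a scalar rate is only valid for M = 2")
    alpha <- matrix(c(0, alpha, alpha, 0), 2, 2)
  }
  alpha <- as_rate_matrix(alpha)
  if (nrow(alpha) != M) stop("alpha must be an M x M matrix")
  z <- stationary_distribution(alpha)
  structure(list(v = v, D = D, L = L, alpha = alpha, M = M, z = z),
            class = "switching_spec")
}

#' Stationary mode weights of the switching process
#'
#' The left null vector `z` of the switching-rate matrix
#' (\eqn{\sum_j z_j \alpha_{ji} = 0}, \eqn{\sum_j z_j = 1}), the marginal
#' probability of each drift mode at stationarity.
#'
#' @param alpha switching-rate matrix (off-diagonal rates; see
#'   [switching_spec()]).
#' @return normalised, non-negative weight vector.
#' @export
switching_stationary_weights <- function(alpha) {
  stationary_distribution(as_rate_matrix(alpha))
}

#' Stationary entropy production of switching diffusion on a ring
#'
#' \deqn{\dot S_i = \sum_i z_i \frac{v_i^2}{D} + \frac12 \sum_{i,j}
#'   (z_i \alpha_{ij} - z_j \alpha_{ji}) \ln\frac{\alpha_{ij}}{\alpha_{ji}}
#'   = -\dot S_e.}
#' The drift-diffusion and mode-switching contributions are independent at
#' steady state: the switching enters the first term only through the
#' stationary weights `z`, so that term is invariant under a time rescaling
#' `alpha -> T alpha`. The second term is the stationary entropy
#' production of the `M`-state switching chain itself; it vanishes for
#' two-mode or detailed-balance switching. A switch `i -> j` with
#' `alpha[j, i] = 0` makes the rate infinite (flagged, not clamped).
#'
#' @param spec a [switching_spec()].
#' @return list with `si` (= `-se`), the two contributions `si_drift`
#'   and `si_switch`, and `flags`.
#' @export
switching_stationary_entropy <- function(spec) {
  stopifnot(inherits(spec, "switching_spec"))
  z <- spec$z
  si_drift <- sum(z * spec$v^2) / spec$D
  a <- unclass(spec$alpha)
  if (any(a > 0 & t(a) == 0)) {
    # a switch whose reverse never happens: infinite entropy per switch event
    return(list(si = Inf, se = -Inf, si_drift = si_drift, si_switch = Inf,
                flags = "irreversible_transition"))
  }
  sw <- entropy_rates(z, spec$alpha, pi = z)
  si_switch <- sw$si
  flags <- sw$flags
  list(si = si_drift + si_switch, se = -(si_drift + si_switch),
       si_drift = si_drift, si_switch = si_switch, flags = flags)
}
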