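#' Two-state Markov process: closed-form solution and entropy rates
#'
#' A particle hops between states 1 and 2 with rates
#' \eqn{w_{12} = \alpha} and \eqn{w_{21} = \beta}. With initial condition
#' \eqn{P(0) = (p, 1-p)} the occupation of state 1 relaxes exponentially,
#' \deqn{P_1(t) = \frac{\beta + r e^{-(\alpha+\beta)t}}{\alpha+\beta},
#'       \quad r = \alpha p - \beta (1 - p),}
#' with probability current \eqn{J_{12}(t) = r e^{-(\alpha+\beta)t}}. The
#' internal entropy production is
#' \eqn{\dot S_i(t) = (P_1\alpha - P_2\beta)\ln\frac{P_1\alpha}{P_2\beta}}
#' and the entropy flow \eqn{\dot S_e(t) = -r e^{-(\alpha+\beta)t}
#' \ln(\alpha/\beta)}. Both vanish as \eqn{t \to \infty}: a two-state
#' network cannot sustain a current, so its steady state is always an
#' equilibrium.
#'
#' @param alpha rate 1 -> 2 (positive).
#' @param beta rate 2 -> 1 (positive).
#' @param p initial probability of state 1.
#' @param t non-negative time(s); vectorised.
#' @return data frame with columns `t`, `P1`, `P2`, `current`, `si`, `se`.
#' @examples
#' two_state_solution(2, 1, p = 1, t = c(0.3, 1, 10))
#' @export
two_state_solution <- function(alpha, beta, p = 1, t) {
  stopifnot(alpha > 0, beta > 0, p >= 0, p <= 1, all(t >= 0))
  r <- alpha * p - beta * (1 - p)
  decay <- exp(-(alpha + beta) * t)
  P1 <- (beta + r * decay) / (alpha + beta)
  P2 <- (alpha - r * decay) / (alpha + beta)
  J <- r * decay
  # si = J ln(P1 a / (P2 b)); 0 ln 0 at J = 0, +Inf when an occupation is 0
  si <- ifelse(J == 0, 0, J * log(P1 * alpha / (P2 * beta)))
  se <- -J * log(alpha / beta)
  data.frame(t = t, P1 = P1, P2 = P2, current = J, si = si, se = se)
}

#' Two-state rate matrix
#' @inheritParams two_state_solution
#' @return a [rate_matrix()] `[[−a, a], [b, −b]]`.
#' @export
two_state_rate_matrix <- function(alpha, beta) {
  rate_matrix(matrix(c(0, alpha, beta, 0), 2, 2, byrow = TRUE))
}

#' Cyclic three-state Markov process: closed-form solution and entropy rates
#'
#' Three states on a ring, forward rate `alpha` (1 -> 2 -> 3 -> 1) and
#' backward rate `beta`, started in state 1. With
#' \eqn{\phi = (\alpha+\beta)/2} and \eqn{\psi = (\alpha-\beta)/2} the
#' occupations are damped oscillations,
#' \deqn{P_1(t) = \tfrac13\left[1 + 2 e^{-3\phi t}
#'       \cos(\sqrt{3}\,\psi t)\right],}
#' with \eqn{P_{2,3}} phase-shifted by \eqn{\mp\pi/3} relative to
#' \eqn{P_1} (and opposite sign of the transient). The entropy flow is
#' constant, \eqn{\dot S_e = -(\alpha-\beta)\ln(\alpha/\beta)}, because the
#' ring sustains a current \eqn{(\alpha-\beta)/3} at stationarity: for
#' \eqn{\alpha \ne \beta} this is a genuine non-equilibrium steady state
#' with \eqn{\dot S_i = -\dot S_e = (\alpha-\beta)\ln(\alpha/\beta) > 0}.
#'
#' @inheritParams two_state_solution
#' @return data frame with columns `t`, `P1`, `P2`, `P3`, `si`, `se`.
#' @export
three_state_solution <- function(alpha, beta, t) {
  stopifnot(alpha > 0, beta > 0, all(t >= 0))
  phi <- (alpha + beta) / 2
  psi <- (alpha - beta) / 2
  damp <- exp(-3 * phi * t)
  th <- sqrt(3) * psi * t
  P1 <- (1 + 2 * damp * cos(th)) / 3
  P2 <- (1 - 2 * damp * cos(th + pi / 3)) / 3
  P3 <- (1 - 2 * damp * cos(th - pi / 3)) / 3
  pair <- function(Pa, Pb) {
    flow <- Pa * alpha - Pb * beta
    ifelse(Pa > 0 & Pb > 0, flow * log(Pa / Pb),
           ifelse(flow == 0, 0, Inf * sign(flow) * ifelse(Pb == 0, 1, -1)))
  }
  si <- (alpha - beta) * log(alpha / beta) +
    pair(P1, P2) + pair(P2, P3) + pair(P3, P1)
  se <- rep(-(alpha - beta) * log(alpha / beta), length(t))
  data.frame(t = t, P1 = P1, P2 = P2, P3 = P3, si = si, se = se)
}

#' Random walk on a complete graph: relaxation and entropy production
#'
#' Uniform hopping rate `alpha` between every pair of `d` nodes. Every
#' initial condition relaxes as
#' \eqn{P_j(t) = 1/d + e^{-d\alpha t}(P_j(0) - 1/d)} towards the uniform
#' distribution. By symmetry of the rates the entropy flow vanishes
#' identically, \eqn{\dot S_e \equiv 0}: all entropy production is due to
#' relaxation and the steady state is an equilibrium. For a point start
#' the internal rate reduces to
#' \deqn{\dot S_i(t) = (d-1)\,\alpha\, e^{-d\alpha t}
#'       \ln\!\left(1 + \frac{d e^{-d\alpha t}}{1 - e^{-d\alpha t}}\right)}
#' with large-time asymptote \eqn{d(d-1)\alpha e^{-2 d \alpha t}}.
#'
#' @param d number of nodes (>= 2).
#' @param alpha uniform hopping rate.
#' @param t non-negative time(s); vectorised.
#' @param p0 initial distribution; default a point start on node 1.
#' @return data frame with columns `t`, `si`, `se` and attribute
#'   `"P"` (matrix of occupations, one row per time).
#' @export
complete_graph_solution <- function(d, alpha, t, p0 = NULL) {
  stopifnot(d >= 2, alpha > 0, all(t >= 0))
  if (is.null(p0)) p0 <- c(1, rep(0, d - 1))
  p0 <- probability_vector(p0)
  if (length(p0) != d) stop("p0 must have length d")
  e <- exp(-d * alpha * t)
  P <- outer(e, p0 - 1 / d) + 1 / d
  # general relaxation form of si: (alpha e / 2) sum_{j,k} (P_j(0)-P_k(0))
  #   ln[(1 + e (d P_j(0) - 1)) / (1 + e (d P_k(0) - 1))]
  si <- vapply(e, function(ee) {
    num <- 1 + ee * (d * p0 - 1)
    s <- 0
    for (j in seq_len(d)) {
      s <- s + sum((p0[j] - p0) * (log(num[j]) - log(num)))
    }
    0.5 * alpha * ee * s
  }, numeric(1))
  out <- data.frame(t = t, si = si, se = rep(0, length(t)))
  attr(out, "P") <- P
  out
}

#' Point-start internal entropy rate on the complete graph
#' @inheritParams complete_graph_solution
#' @return \eqn{\dot S_i(t)} for a walker started on a single node.
#' @export
complete_graph_point_si <- function(d, alpha, t) {
  e <- exp(-d * alpha * t)
  ifelse(e >= 1, Inf, (d - 1) * alpha * e * log(1 + d * e / (1 - e)))
}

#' Large-time asymptote of the complete-graph entropy rate
#' @inheritParams complete_graph_solution
#' @return \eqn{d (d-1) \alpha e^{-2 d \alpha t}}.
#' @export
complete_graph_si_asymptote <- function(d, alpha, t) {
  d * (d - 1) * alpha * exp(-2 * d * alpha * t)
}
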