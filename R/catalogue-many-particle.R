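#' Entropy rates of independent, distinguishable processes
#'
#' For `N` non-interacting distinguishable particles the joint distribution
#' factorises and both the internal entropy production and the entropy flow
#' of the product chain are the sums of the single-particle contributions,
#' irrespective of how each particle is initialised.
#'
#' @param systems a list whose elements are lists with components `p`
#'   (probability vector) and `W` ([rate_matrix()]), one per particle.
#' @return an `"entropy_rates"` object with summed `si`, `se`, `sdot` and
#'   `S` (the adiabatic split is not propagated).
#' @export
distinguishable_sum <- function(systems) {
  if (length(systems) == 0L) stop("need at least one single-particle system")
  parts <- lapply(systems, function(s) entropy_rates(s$p, s$W, pi = NA))
  tot <- function(f) sum(vapply(parts, `[[`, numeric(1), f))
  structure(list(S = tot("S"), sdot = tot("sdot"), si = tot("si"),
                 se = tot("se"), sia = NA_real_, sina = NA_real_,
                 flags = unique(unlist(lapply(parts, `[[`, "flags")))),
            class = "entropy_rates")
}

#' Product chain of independent distinguishable particles
#'
#' Builds the full rate matrix on the product state space (used as the
#' brute-force cross-check of [distinguishable_sum()]; exponential in the
#' particle number, keep it small).
#'
#' @param Ws list of single-particle rate matrices.
#' @return a [rate_matrix()] on `prod(d_l)` states, labelled `"n1.n2..."`.
#' @export
product_chain <- function(Ws) {
  Ws <- lapply(Ws, as_rate_matrix)
  dims <- vapply(Ws, nrow, integer(1))
  states <- as.matrix(expand.grid(lapply(dims, seq_len)))
  ns <- nrow(states)
  w <- matrix(0, ns, ns)
  for (a in seq_len(ns)) {
    for (l in seq_along(Ws)) {
      for (m in seq_len(dims[l])) {
        if (m == states[a, l]) next
        to <- states[a, ]
        to[l] <- m
        b <- which(apply(states, 1, function(s) all(s == to)))
        w[a, b] <- w[a, b] + Ws[[l]][states[a, l], m]
      }
    }
  }
  rate_matrix(w, labels = apply(states, 1, paste, collapse = "."))
}

#' Product distribution of independent particles
#' @param ps list of single-particle probability vectors (same order as in
#'   [product_chain()]).
#' @return probability vector over the product state space.
#' @export
product_distribution <- function(ps) {
  states <- as.matrix(expand.grid(lapply(lengths(ps), seq_len)))
  apply(states, 1, function(s) prod(mapply(function(p, i) p[i], ps, s)))
}

#' N indistinguishable two-state particles: occupation process
#'
#' `N` identical, non-interacting particles each following the two-state
#' process of [two_state_solution()]. The system state is the occupation
#' number `n` of state 1 (`N + 1` states). Provided the initial occupation
#' is binomial with per-particle probability `p`, it stays binomial with
#' \eqn{P_1(t)} of the single particle, and the internal entropy production
#' is exactly `N` times the single-particle one. The entropy flow picks up
#' a combinatorial correction,
#' \deqn{\dot S_e(t) = -N\left[\alpha P_1 - \beta(1-P_1)\right]
#'   \left\{\ln\frac{\alpha}{\beta} + \sum_{n=0}^{N-1}
#'   \binom{N-1}{n} P_1^n (1-P_1)^{N-1-n}
#'   \ln\frac{n+1}{N-n}\right\},}
#' a difference of microcanonical entropies of the occupation states; it
#' vanishes at `N = 1`, at \eqn{P_1 = 1/2}, and at stationarity.
#'
#' @param N particle number (>= 1).
#' @inheritParams two_state_solution
#' @return data frame with columns `t`, `P1`, `si`, `se`; attribute
#'   `"occupation"` holds the matrix of occupation-number probabilities
#'   `P(n, t)` (rows: times, cols: `n = 0..N`).
#' @export
indistinguishable_two_state <- function(N, alpha, beta, p = 1, t) {
  stopifnot(N >= 1, alpha > 0, beta > 0)
  single <- two_state_solution(alpha, beta, p, t)
  P1 <- single$P1
  si <- N * single$si
  corr <- vapply(P1, function(q) {
    n <- 0:(N - 1)
    sum(stats::dbinom(n, N - 1, q) * log((n + 1) / (N - n)))
  }, numeric(1))
  flow <- alpha * P1 - beta * (1 - P1)
  se <- -N * flow * (log(alpha / beta) + corr)
  occ <- t(vapply(P1, function(q) stats::dbinom(0:N, N, q), numeric(N + 1)))
  colnames(occ) <- 0:N
  out <- data.frame(t = t, P1 = P1, si = si, se = se)
  attr(out, "occupation") <- occ
  out
}

#' Occupation-number chain of N two-state particles
#'
#' Rate matrix on occupation numbers `n = 0..N` of state 1:
#' `n -> n - 1` at rate `alpha * n`, `n -> n + 1` at rate
#' `beta * (N - n)`. Used as the engine-level cross-check of
#' [indistinguishable_two_state()].
#'
#' @inheritParams indistinguishable_two_state
#' @return a [rate_matrix()] on `N + 1` states labelled by `n`.
#' @export
occupation_chain_two_state <- function(N, alpha, beta) {
  d <- N + 1L
  w <- matrix(0, d, d)
  for (n in 0:N) {
    i <- n + 1L
    if (n > 0) w[i, i - 1L] <- alpha * n
    if (n < N) w[i, i + 1L] <- beta * (N - n)
  }
  rate_matrix(w, labels = as.character(0:N))
}

# enumerate all occupation vectors of N particles on d sites
occupation_states <- function(N, d) {
  if (d == 1L) return(matrix(N, 1, 1))
  out <- NULL
  for (n1 in 0:N) {
    rest <- occupation_states(N - n1, d - 1L)
    out <- rbind(out, cbind(n1, rest))
  }
  unname(out)
}

#' N indistinguishable d-state particles: entropy rates
#'
#' `N` identical non-interacting particles on a graph of `d` states with
#' single-particle rate matrix `W`, all initialised with the same
#' single-particle distribution so that the occupation-number distribution
#' is multinomial at all times. The internal entropy production is exactly
#' `N` times the single-particle one,
#' \eqn{\dot S_i = N \dot S_i^{(1)}}. The entropy flow is
#' \eqn{N \dot S_e^{(1)}} plus a microcanonical correction
#' \eqn{-\sum_{\mathbf n} \dot P_{\mathbf n}
#' \ln \binom{N}{n_1, \dots, n_d}} (a difference of Boltzmann entropies of
#' the occupation states) which vanishes at stationarity. The correction is
#' evaluated by exact enumeration of the occupation states, so keep
#' `choose(N + d - 1, d - 1)` modest.
#'
#' @param N particle number.
#' @param W single-particle [rate_matrix()] (`d` states).
#' @param p single-particle distribution at the time of interest.
#' @return an `"entropy_rates"`-like list with `si`, `se`, `si1`, `se1`
#'   (single-particle values) and `correction`.
#' @export
indistinguishable_dstate <- function(N, W, p) {
  W <- as_rate_matrix(W)
  p <- probability_vector(p)
  d <- nrow(W)
  if (length(p) != d) stop("p must have one entry per state of W")
  single <- entropy_rates(p, W, pi = NA)
  states <- occupation_states(N, d)
  pdot1 <- as.vector(p %*% unclass(W))
  lp <- ifelse(p > 0, log(p), -Inf)
  Pn <- apply(states, 1, function(n) exp(lgamma(N + 1) - sum(lgamma(n + 1)) +
                                           sum(ifelse(n > 0, n * lp, 0))))
  # d/dt of the multinomial weight: P_n * sum_j n_j pdot_j / p_j
  Pdot <- vapply(seq_len(nrow(states)), function(i) {
    n <- states[i, ]
    ok <- n > 0
    if (any(ok & p == 0)) return(0)  # weight itself is zero
    Pn[i] * sum(n[ok] * pdot1[ok] / p[ok])
  }, numeric(1))
  lmulti <- apply(states, 1, function(n) lgamma(N + 1) - sum(lgamma(n + 1)))
  correction <- -sum(Pdot * lmulti)
  list(si = N * single$si, se = N * single$se + correction,
       si1 = single$si, se1 = single$se, correction = correction)
}

#' Occupation-number chain of N particles on a d-state graph
#'
#' Full rate matrix on occupation vectors `(n_1, ..., n_d)` with
#' `sum(n) = N`: a particle hop `j -> k` moves the system at rate
#' `n_j * w[j, k]`. Brute-force cross-check of
#' [indistinguishable_dstate()].
#'
#' @inheritParams indistinguishable_dstate
#' @return list with `W` (the occupation [rate_matrix()]) and `states`
#'   (matrix of occupation vectors, one row per chain state).
#' @export
occupation_chain <- function(N, W) {
  W <- as_rate_matrix(W)
  d <- nrow(W)
  states <- occupation_states(N, d)
  key <- apply(states, 1, paste, collapse = ",")
  idx <- stats::setNames(seq_along(key), key)
  ns <- nrow(states)
  w <- matrix(0, ns, ns)
  for (a in seq_len(ns)) {
    n <- states[a, ]
    for (j in seq_len(d)) {
      if (n[j] == 0) next
      for (k in seq_len(d)) {
        if (k == j || W[j, k] == 0) next
        m <- n
        m[j] <- m[j] - 1L
        m[k] <- m[k] + 1L
        b <- idx[[paste(m, collapse = ",")]]
        w[a, b] <- w[a, b] + n[j] * W[j, k]
      }
    }
  }
  list(W = rate_matrix(w, labels = key), states = states)
}

#' Multinomial occupation distribution
#' @inheritParams indistinguishable_dstate
#' @param states occupation-state matrix as returned by [occupation_chain()].
#' @return probability vector over the occupation states.
#' @export
multinomial_occupation <- function(N, p, states) {
  p <- probability_vector(p)
  lp <- ifelse(p > 0, log(p), -Inf)
  apply(states, 1, function(n) exp(lgamma(N + 1) - sum(lgamma(n + 1)) +
                                     sum(ifelse(n > 0, n * lp, 0))))
}
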