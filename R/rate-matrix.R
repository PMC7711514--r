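#' Construct and validate a continuous-time Markov rate matrix
#'
#' Builds a `rate_matrix` from the off-diagonal transition rates of a
#' continuous-time Markov chain. Row `n`, column `m` holds the rate
#' \eqn{w_{nm}} of jumping from state `n` to state `m`. The diagonal is
#' always (re)filled with \eqn{w_{nn} = -\sum_{m \ne n} w_{nm}} so that every
#' row sums to zero, the conservation-of-probability condition of the master
#' equation.
#'
#' @param rates square numeric matrix of non-negative off-diagonal rates
#'   (per unit time). Diagonal entries are ignored and overwritten.
#' @param labels optional character vector of state labels; defaults to the
#'   dimnames of `rates` or `"1".."d"`.
#' @return a `rate_matrix`: a numeric matrix with zero row sums, state labels
#'   as dimnames and class `c("rate_matrix", "matrix")`.
#' @examples
#' rate_matrix(matrix(c(0, 2, 1, 0), 2, 2, byrow = TRUE))
#' @seealso [solve_master()], [stationary_distribution()], [entropy_rates()]
#' @export
rate_matrix <- function(rates, labels = NULL) {
  rates <- as.matrix(rates)
  if (nrow(rates) != ncol(rates)) {
    stop("rate matrix must be square, got ", nrow(rates), " x ", ncol(rates))
  }
  d <- nrow(rates)
  if (d < 2L) stop("a rate matrix needs at least 2 states")
  if (!is.numeric(rates) || anyNA(rates)) {
    stop("rates must be numeric and free of NA")
  }
  off <- rates[row(rates) != col(rates)]
  if (any(off < 0)) stop("off-diagonal transition rates must be non-negative")
  diag(rates) <- 0
  diag(rates) <- -rowSums(rates)
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(rates))) rownames(rates) else as.character(seq_len(d))
  }
  if (length(labels) != d) stop("need exactly ", d, " state labels")
  dimnames(rates) <- list(labels, labels)
  class(rates) <- c("rate_matrix", "matrix")
  rates
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("Rate matrix on", nrow(x), "states (rows: origin, cols: destination)\n")
  print(unclass(x), ...)
  invisible(x)
}

is_rate_matrix <- function(W, tol = 1e-12) {
  is.matrix(W) && nrow(W) == ncol(W) &&
    all(W[row(W) != col(W)] >= 0) &&
    max(abs(rowSums(W))) <= tol * max(1, max(abs(W)))
}

as_rate_matrix <- function(W) {
  if (inherits(W, "rate_matrix")) W else rate_matrix(W, labels = rownames(W))
}

#' Validate a probability vector
#'
#' @param p numeric vector; entries must be non-negative and sum to one
#'   within `tol`.
#' @param tol tolerance on the normalisation.
#' @return `p`, renormalised exactly.
#' @export
probability_vector <- function(p, tol = 1e-12) {
  if (any(p < -tol)) stop("probabilities must be non-negative")
  p[p < 0] <- 0
  s <- sum(p)
  if (abs(s - 1) > 1e-8) stop("probabilities must sum to 1, got ", format(s))
  p / s
}

#' Solve the master equation
#'
#' Propagates an initial distribution through \eqn{P(t) = P(0) e^{w t}}
#' (row-vector convention), using the matrix exponential of the rate matrix.
#'
#' @param W a [rate_matrix()].
#' @param p0 initial probability vector.
#' @param times non-negative, non-decreasing time grid.
#' @return a matrix with one row per time point and one column per state,
#'   with attribute `"times"`; class `"prob_trajectory"`.
#' @examples
#' W <- rate_matrix(matrix(c(0, 1, 1, 0), 2, 2))
#' solve_master(W, c(1, 0), c(0, 1, 10))
#' @export
solve_master <- function(W, p0, times) {
  W <- as_rate_matrix(W)
  p0 <- probability_vector(p0)
  if (length(p0) != nrow(W)) stop("p0 length does not match the number of states")
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times)) stop("times must be non-decreasing")
  out <- matrix(NA_real_, length(times), nrow(W),
                dimnames = list(NULL, rownames(W)))
  # step incrementally: expm of the increment, reusing the evolving state
  p <- p0
  t_prev <- 0
  for (i in seq_along(times)) {
    dt <- times[i] - t_prev
    if (dt > 0) {
      p <- as.vector(p %*% as.matrix(Matrix::expm(Matrix::Matrix(unclass(W) * dt))))
      # clip tiny negative round-off and renormalise
      p[p < 0] <- 0
      p <- p / sum(p)
      t_prev <- times[i]
    }
    out[i, ] <- p
  }
  attr(out, "times") <- times
  class(out) <- c("prob_trajectory", "matrix")
  out
}

#' @export
print.prob_trajectory <- function(x, ...) {
  cat("Probability trajectory:", nrow(x), "time points,", ncol(x), "states\n")
  df <- data.frame(time = attr(x, "times"), unclass(x), check.names = FALSE)
  print(utils::head(df, 10), ...)
  if (nrow(df) > 10) cat("...\n")
  invisible(x)
}

#' Stationary distribution of a rate matrix
#'
#' Finds the left null vector \eqn{\pi w = 0}, normalised to a probability
#' vector. The stationary state must be unique: the zero eigenvalue of the
#' rate matrix has to be simple within `tol` of the spectral gap, otherwise
#' the chain has several ergodic components and the limit distribution
#' depends on the initial condition.
#'
#' @param W a [rate_matrix()].
#' @param tol tolerance used to decide simplicity of the zero eigenvalue.
#' @return stationary probability vector `pi`.
#' @export
stationary_distribution <- function(W, tol = 1e-10) {
  W <- as_rate_matrix(W)
  ev <- eigen(t(unclass(W)))
  scale <- max(1, max(abs(unclass(W))))
  near_zero <- which(abs(ev$values) <= tol * scale)
  if (length(near_zero) == 0L) {
    # always present analytically; numerically take the smallest magnitude
    near_zero <- which.min(abs(ev$values))
  }
  if (length(near_zero) > 1L) {
    stop(structure(
      class = c("entroprod_multiple_stationary", "error", "condition"),
      list(message = paste0(
        "zero eigenvalue of the rate matrix is degenerate (multiplicity ",
        length(near_zero), "): the chain has several ergodic components ",
        "and no unique stationary distribution"),
        call = sys.call(-1))))
  }
  v <- Re(ev$vectors[, near_zero])
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-8 * max(abs(v)))) {
    stop("stationary eigenvector has mixed signs; rate matrix may be invalid")
  }
  v[v < 0] <- 0
  pi <- v / sum(v)
  names(pi) <- rownames(W)
  pi
}

#' Probability currents of a chain at a given distribution
#'
#' \eqn{J_{nm} = P_n w_{nm} - P_m w_{mn}}, the net probability flow from
#' state `n` to state `m`. The matrix is antisymmetric and vanishes
#' identically iff global detailed balance holds at `p`.
#'
#' @inheritParams solve_master
#' @param p probability vector.
#' @return antisymmetric matrix of currents (per unit time).
#' @export
probability_currents <- function(p, W) {
  W <- as_rate_matrix(W)
  p <- probability_vector(p)
  J <- p * unclass(W) - t(p * unclass(W))
  diag(J) <- 0
  dimnames(J) <- dimnames(W)
  J
}

#' Detailed-balance residual at stationarity
#'
#' Maximum over state pairs of \eqn{|\pi_n w_{nm} - \pi_m w_{mn}|}. Zero
#' means the stationary state is an equilibrium (no stationary currents, no
#' stationary entropy production); a positive value is the fingerprint of a
#' non-equilibrium steady state.
#'
#' @inheritParams stationary_distribution
#' @return non-negative scalar.
#' @export
detailed_balance_residual <- function(W) {
  W <- as_rate_matrix(W)
  pi <- stationary_distribution(W)
  max(abs(probability_currents(pi, W)))
}

#' Random rate matrices for testing and exploration
#'
#' Generates reproducible random rate matrices. Mode `"generic"` draws
#' i.i.d. positive off-diagonal rates; `"detailed_balance"` builds
#' \eqn{w_{nm} = r_{nm} e^{(E_n - E_m)/2}} from a symmetric positive matrix
#' `r` and random state energies `E`, which guarantees an equilibrium
#' steady state (Boltzmann weights \eqn{\pi_n \propto e^{-E_n}});
#' `"cyclic"` produces a one-dimensional ring with uniform forward rate
#' `alpha` and backward rate `beta`.
#'
#' @param d number of states (at least 2).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param mode one of `"generic"`, `"detailed_balance"`, `"cyclic"`.
#' @param alpha,beta forward/backward rates used by `mode = "cyclic"`.
#' @return a [rate_matrix()].
#' @export
random_rate_matrix <- function(d, seed = NULL,
                               mode = c("generic", "detailed_balance", "cyclic"),
                               alpha = 2, beta = 1) {
  mode <- match.arg(mode)
  if (d < 2L) stop("need at least d = 2 states")
  if (!is.null(seed)) set.seed(seed)
  if (mode == "cyclic") return(cyclic_rate_matrix(d, alpha, beta))
  if (mode == "generic") {
    w <- matrix(stats::rexp(d * d), d, d)
  } else {
    r <- matrix(stats::rexp(d * d), d, d)
    r <- (r + t(r)) / 2
    E <- stats::rnorm(d)
    w <- r * exp((E - rep(E, each = d)) / 2)  # w[n,m] = r[n,m] exp((E_n - E_m)/2)
  }
  rate_matrix(w)
}

#' Cyclic (ring) rate matrix
#'
#' `d`-state ring with rate `alpha` for the forward step `i -> i+1 (mod d)`
#' and `beta` for the backward step. For `alpha != beta` the stationary
#' state is uniform but carries a current `(alpha - beta)/d` along every
#' edge, the minimal model of a driven conformational cycle.
#'
#' @param d number of states on the ring (>= 2).
#' @param alpha forward rate.
#' @param beta backward rate.
#' @return a [rate_matrix()].
#' @export
cyclic_rate_matrix <- function(d, alpha, beta) {
  if (d < 2L) stop("need at least d = 2 states")
  if (alpha < 0 || beta < 0) stop("rates must be non-negative")
  w <- matrix(0, d, d)
  idx <- seq_len(d)
  w[cbind(idx, idx %% d + 1L)] <- alpha
  w[cbind(idx, (idx - 2L) %% d + 1L)] <- w[cbind(idx, (idx - 2L) %% d + 1L)] + beta
  rate_matrix(w)
}

#' Complete-graph rate matrix with uniform rates
#'
#' Every ordered pair of distinct states is connected with the same rate
#' `alpha`. The spectrum has a simple zero eigenvalue and a single
#' relaxation rate `d * alpha` with multiplicity `d - 1`.
#'
#' @param d number of nodes.
#' @param alpha uniform hopping rate.
#' @return a [rate_matrix()].
#' @export
complete_graph_rate_matrix <- function(d, alpha = 1) {
  if (d < 2L) stop("need at least d = 2 states")
  w <- matrix(alpha, d, d)
  rate_matrix(w)
}
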