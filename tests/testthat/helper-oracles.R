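# Independent oracles used across the suite.

# high-accuracy ODE integration of the master equation (independent of the
# package's matrix-exponential path)
ode_master <- function(W, p0, times) {
  w <- unclass(W)
  sol <- deSolve::lsoda(
    y = p0, times = c(0, times),
    func = function(t, p, parms) list(as.vector(p %*% w)),
    rtol = 1e-12, atol = 1e-14)
  unname(sol[-1, -1, drop = FALSE])
}

# centered finite difference of the Shannon entropy along the solved
# trajectory, an oracle for sdot = si + se
fd_entropy_rate <- function(W, p0, t, h = 1e-5) {
  tr <- solve_master(W, p0, c(t - h, t + h))
  (shannon_entropy(tr[2, ]) - shannon_entropy(tr[1, ])) / (2 * h)
}

# random probability vector with strictly positive entries
random_prob <- function(d) {
  p <- stats::rgamma(d, shape = 1) + 1e-3
  p / sum(p)
}

expect_close <- function(object, expected, tol = 1e-10) {
  expect_true(max(abs(object - expected)) <= tol,
              label = sprintf("max|diff| = %g (tol %g)",
                              max(abs(object - expected)), tol))
}
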