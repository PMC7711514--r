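test_that("rate_matrix fills the diagonal and enforces validity", {
  W <- rate_matrix(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(diag(unclass(W)), c("1" = -1, "2" = -1))
  expect_equal(rowSums(unclass(W)), c("1" = 0, "2" = 0))

  # generic off-diagonal input: row sums still vanish whatever the diagonal was
  W3 <- rate_matrix(matrix(c(9, 2, 1, 1, 9, 2, 2, 1, 9), 3, 3, byrow = TRUE))
  expect_equal(unname(rowSums(unclass(W3))), rep(0, 3))

  expect_error(rate_matrix(matrix(1, 2, 3)), "square")
  expect_error(rate_matrix(matrix(c(0, -1, 1, 0), 2, 2)), "non-negative")
  expect_error(rate_matrix(matrix(0, 1, 1)), "at least 2")
})

test_that("two-state rates alpha = beta give the symmetric matrix", {
  W <- two_state_rate_matrix(1, 1)
  expect_equal(unname(unclass(W)), matrix(c(-1, 1, 1, -1), 2, 2, byrow = TRUE))
})

test_that("solve_master matches closed forms and an independent ODE oracle", {
  # symmetric two-state chain relaxes to 1/2
  W <- two_state_rate_matrix(1, 1)
  tr <- solve_master(W, c(1, 0), c(0, 50))
  expect_close(tr[2, ], c(0.5, 0.5), 1e-12)

  # general two-state closed form
  a <- 2; b <- 1; p <- 0.8
  r <- a * p - b * (1 - p)
  ts <- c(0.1, 0.5, 2)
  tr <- solve_master(two_state_rate_matrix(a, b), c(p, 1 - p), ts)
  expect_close(tr[, 1], (b + r * exp(-(a + b) * ts)) / (a + b), 1e-12)

  # random 4-state chain against high-accuracy ODE integration
  skip_if_not_installed("deSolve")
  W4 <- random_rate_matrix(4, seed = 11, mode = "generic")
  p0 <- c(0.4, 0.3, 0.2, 0.1)
  ts <- c(0.2, 0.7, 1.5)
  expect_close(unclass(solve_master(W4, p0, ts)), ode_master(W4, p0, ts), 1e-10)

  expect_error(solve_master(W, c(1, 0), c(-1, 0)), "non-negative")
  expect_error(solve_master(W, c(0.5, 0.6), 1), "sum to 1")
})

test_that("stationary_distribution recovers known steady states", {
  expect_close(stationary_distribution(two_state_rate_matrix(2, 1)),
               c(1, 2) / 3, 1e-12)
  expect_close(stationary_distribution(cyclic_rate_matrix(3, 2, 1)),
               rep(1 / 3, 3), 1e-12)
  expect_close(stationary_distribution(complete_graph_rate_matrix(6, 1)),
               rep(1 / 6, 6), 1e-12)
})

test_that("disconnected chains are refused, not silently resolved", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 2
  expect_error(stationary_distribution(rate_matrix(w)), "ergodic components")
  expect_error(detailed_balance_residual(rate_matrix(w)), "ergodic components")
})

test_that("probability currents are antisymmetric and vanish at equilibrium", {
  W <- two_state_rate_matrix(2, 1)
  expect_close(probability_currents(c(1, 2) / 3, W), matrix(0, 2, 2), 1e-14)

  # transient two-state current decays as r e^{-(a+b)t}
  a <- 2; b <- 1; p <- 1
  t <- 0.4
  tr <- solve_master(two_state_rate_matrix(a, b), c(p, 1 - p), t)
  J <- probability_currents(tr[1, ], two_state_rate_matrix(a, b))
  expect_equal(J[1, 2], (a * p - b * (1 - p)) * exp(-(a + b) * t), tolerance = 1e-10)
  expect_equal(unname(J), -t(unname(J)))

  # stationary ring current (alpha - beta)/d on every edge
  Jc <- probability_currents(rep(1 / 3, 3), cyclic_rate_matrix(3, 2, 1))
  expect_close(Jc[cbind(1:3, c(2, 3, 1))], rep(1 / 3, 3), 1e-12)
})

test_that("detailed-balance construction yields equilibrium chains", {
  for (seed in 1:5) {
    W <- random_rate_matrix(5, seed = seed, mode = "detailed_balance")
    expect_lt(detailed_balance_residual(W), 1e-12)
  }
  # driven ring is genuinely out of equilibrium
  expect_gt(detailed_balance_residual(cyclic_rate_matrix(3, 2, 1)), 0.1)
  # any two-state chain satisfies detailed balance at stationarity
  expect_lt(detailed_balance_residual(two_state_rate_matrix(5, 0.3)), 1e-12)
})

test_that("random_rate_matrix is reproducible and cyclic mode has ring structure", {
  expect_identical(random_rate_matrix(4, seed = 3),
                   random_rate_matrix(4, seed = 3))
  W <- random_rate_matrix(3, seed = 1, mode = "cyclic", alpha = 2, beta = 1)
  expect_equal(unname(unclass(W)),
               matrix(c(-3, 2, 1, 1, -3, 2, 2, 1, -3), 3, 3, byrow = TRUE))
  expect_error(random_rate_matrix(1, seed = 1), "at least")
})
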