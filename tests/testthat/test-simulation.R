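test_that("jump-path sampler is seeded, exact and respects occupancy", {
  W <- two_state_rate_matrix(1, 1)
  expect_identical(sample_jump_paths(W, c(1, 0), 10, 5, seed = 3),
                   sample_jump_paths(W, c(1, 0), 10, 5, seed = 3))
  # symmetric chain: time-averaged occupancy of state 1 near 1/2
  paths <- sample_jump_paths(W, c(1, 0), horizon = 10, n_paths = 400, seed = 1)
  occ <- vapply(seq_along(paths$states), function(i) {
    st <- paths$states[[i]]; tm <- c(paths$times[[i]], paths$horizon)
    sum(diff(tm)[st == 1]) / paths$horizon
  }, numeric(1))
  expect_lt(abs(mean(occ) - 0.5), 3 * stats::sd(occ) / sqrt(length(occ)))
  # path structure invariants
  for (i in 1:5) {
    tm <- paths$times[[i]]
    expect_true(all(diff(tm) > 0))
    expect_true(all(tm <= paths$horizon))
    expect_true(all(paths$states[[i]] %in% 1:2))
  }
  # absorbing state: path ends there and is flagged
  wab <- matrix(0, 2, 2); wab[1, 2] <- 1
  pab <- sample_jump_paths(rate_matrix(wab), c(1, 0), 50, 10, seed = 2)
  expect_true(all(pab$absorbed))
})

test_that("medium entropy estimator converges to the stationary production", {
  W <- cyclic_rate_matrix(3, 2, 1)
  paths <- sample_jump_paths(W, rep(1 / 3, 3), horizon = 20, n_paths = 800, seed = 7)
  m <- medium_entropy_rate(paths, W)
  expect_lt(abs(m$estimate - log(2)), 3 * m$se)
  # empirical edge current matches (alpha - beta)/3
  J <- empirical_currents(paths)
  expect_equal(J[1, 2], 1 / 3, tolerance = 0.05)
  # detailed-balance chain: zero within the confidence interval
  Wdb <- random_rate_matrix(3, seed = 4, mode = "detailed_balance")
  pdb <- sample_jump_paths(Wdb, stationary_distribution(Wdb), 20, 400, seed = 8)
  mdb <- medium_entropy_rate(pdb, Wdb)
  expect_lt(abs(mdb$estimate), 3 * mdb$se)
  # biased lattice walk: -se = (r - l) ln(r/l) per unit time
  sp <- lattice_rw(1.5, 0.5)
  Wl <- lattice_rw_chain(sp, 80)
  pl <- sample_jump_paths(Wl, as.numeric(-80:80 == 0), 15, 400, seed = 9)
  ml <- medium_entropy_rate(pl, Wl)
  expect_lt(abs(ml$estimate - log(3)), 3 * ml$se)
  # a jump over an irreversible edge makes the estimate infinite
  wab <- matrix(0, 2, 2); wab[1, 2] <- 1; wab[2, 1] <- 0
  pab <- sample_jump_paths(rate_matrix(wab), c(1, 0), 50, 5, seed = 2)
  mab <- medium_entropy_rate(pab, rate_matrix(wab))
  expect_identical(mab$estimate, Inf)
  expect_true("irreversible_transition" %in% mab$flags)
})

test_that("path-KL estimator approaches the entropy production as tau shrinks", {
  W <- cyclic_rate_matrix(3, 2, 1)
  paths <- sample_jump_paths(W, rep(1 / 3, 3), horizon = 20, n_paths = 400, seed = 11)
  taus <- c(0.1, 0.05, 0.025)
  ests <- vapply(taus, function(tau) path_kl_rate(paths, W, tau)$estimate,
                 numeric(1))
  # finite-sampling bias is positive downward and shrinks monotonically
  expect_true(all(diff(ests) > 0))
  expect_true(all(ests < log(2) + 0.05))
  expect_lt(abs(ests[3] - log(2)) / log(2), 0.25)
  # stationary two-state chain: no time-reversal asymmetry
  W2 <- two_state_rate_matrix(2, 1)
  p2 <- sample_jump_paths(W2, c(1, 2) / 3, 20, 200, seed = 12)
  k2 <- path_kl_rate(p2, W2, 0.05)
  expect_lt(abs(k2$estimate), 3 * max(k2$se, 1e-4))
})

test_that("Euler-Maruyama reproduces known moments and is seeded", {
  sp <- diffusion_spec(v = 0, D = 1)
  pa <- euler_maruyama(sp, dt = 0.01, horizon = 5, n_paths = 1500, seed = 1, x0 = 0)
  xT <- pa$x[nrow(pa$x), ]
  expect_lt(abs(stats::var(xT) - 10) / 10, 0.15)   # var = 2 D T
  expect_identical(pa$x, euler_maruyama(sp, 0.01, 5, 1500, seed = 1, x0 = 0)$x)
  # harmonic confinement: stationary variance D/k (Boltzmann form)
  spo <- diffusion_spec(v = 0, D = 1, k = 2)
  po <- euler_maruyama(spo, dt = 0.01, horizon = 10, n_paths = 1500, seed = 2, x0 = 0)
  expect_lt(abs(stats::var(po$x[nrow(po$x), ]) - 0.5) / 0.5, 0.15)
  # unstable steps are refused with a suggestion
  expect_error(euler_maruyama(diffusion_spec(k = 100), 0.01, 1, 10), "dt too large")
  expect_error(euler_maruyama(switching_spec(c(1, -1), 1, 1, alpha = 100),
                              0.01, 1, 10), "dt too large")
})

test_that("Stratonovich heat estimator recovers stationary entropy production", {
  # driven ring without potential: si = v^2/D
  spr <- diffusion_spec(v = 1, D = 1, domain = "ring", L = 1)
  pr <- euler_maruyama(spr, dt = 0.005, horizon = 10, n_paths = 1200, seed = 3,
                       x0 = "stationary")
  sm <- stratonovich_medium_entropy(pr)
  expect_lt(abs(sm$estimate - 1), 3 * sm$se)
  # equilibrium harmonic confinement: Stratonovich heat is zero on average,
  # while the Ito evaluation measures <F^2>/D = k instead
  spo <- diffusion_spec(v = 0, D = 1, k = 1)
  po <- euler_maruyama(spo, dt = 0.005, horizon = 20, n_paths = 400, seed = 4, x0 = 0)
  half <- (nrow(po$x) - 1) %/% 2
  po$x <- po$x[-(1:half), ]   # discard the relaxation transient
  po$horizon <- po$horizon / 2
  ss <- stratonovich_medium_entropy(po)
  si_ito <- stratonovich_medium_entropy(po, convention = "ito")
  expect_lt(abs(ss$estimate), 3 * ss$se)
  expect_gt(si_ito$estimate, 0.7)   # ~ k = 1, clearly distinct from zero
})

test_that("run-and-tumble and switching simulations meet their analytic rates", {
  sw <- switching_spec(c(1, -2), D = 1, L = 1, alpha = 1)
  pw <- euler_maruyama(sw, dt = 0.002, horizon = 10, n_paths = 1200, seed = 5)
  mw <- stratonovich_medium_entropy(pw)
  expect_lt(abs(mw$estimate - 2.5), 3 * mw$se)
  # symmetric two-mode switching contributes exactly zero
  ms <- mode_switch_entropy(pw)
  expect_identical(ms$estimate, 0)
  # cyclic three-mode switching: switching term ln 2 within the CI
  a3 <- cyclic_rate_matrix(3, 2, 1)
  s3 <- switching_spec(c(1, 0, -1), D = 1, L = 1, alpha = unclass(a3))
  p3 <- euler_maruyama(s3, dt = 0.002, horizon = 10, n_paths = 1200, seed = 6)
  m3 <- mode_switch_entropy(p3)
  expect_lt(abs(m3$estimate - log(2)), 3 * m3$se)
  # drift part unchanged under alpha -> 10 alpha (time-rescaling invariance)
  s3f <- switching_spec(c(1, 0, -1), D = 1, L = 1, alpha = 10 * unclass(a3))
  p3f <- euler_maruyama(s3f, dt = 0.002, horizon = 10, n_paths = 600, seed = 6)
  d1 <- stratonovich_medium_entropy(p3)
  d2 <- stratonovich_medium_entropy(p3f)
  expect_lt(abs(d1$estimate - d2$estimate), 3 * sqrt(d1$se^2 + d2$se^2))
})

test_that("estimator error shrinks with the sample size", {
  W <- cyclic_rate_matrix(3, 2, 1)
  errs <- vapply(c(100, 900), function(n) {
    p <- sample_jump_paths(W, rep(1 / 3, 3), horizon = 10, n_paths = n, seed = 21)
    abs(medium_entropy_rate(p, W)$estimate - log(2))
  }, numeric(1))
  ses <- vapply(c(100, 900), function(n) {
    p <- sample_jump_paths(W, rep(1 / 3, 3), horizon = 10, n_paths = n, seed = 21)
    medium_entropy_rate(p, W)$se
  }, numeric(1))
  # the reported standard error scales like 1/sqrt(n): ratio ~ 3
  expect_equal(ses[1] / ses[2], 3, tolerance = 0.5)
  expect_lt(errs[2], 3 * ses[2])
})
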