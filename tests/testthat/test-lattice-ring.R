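test_that("lattice density: point start, symmetry, normalisation, oracle", {
  sp <- lattice_rw(1.5, 0.5)
  expect_equal(lattice_rw_density(sp, -2:2, 0), c(0, 0, 1, 0, 0))
  # symmetric walk: even in x - x0
  sps <- lattice_rw(1, 1)
  expect_close(lattice_rw_density(sps, 1:5, 2), lattice_rw_density(sps, -(1:5), 2), 1e-15)
  # sums to one over a wide window
  expect_equal(sum(lattice_rw_density(sp, -60:64, 2)), 1, tolerance = 1e-12)
  # off-lattice positions are rejected
  expect_error(lattice_rw_density(sp, 0.5, 1), "lattice")
  # truncated-chain oracle (+-60 sites)
  W <- lattice_rw_chain(sp, 60)
  tr <- solve_master(W, as.numeric(-60:60 == 0), 2)
  expect_close(lattice_rw_density(sp, -60:60, 2), tr[1, ], 1e-8)
})

test_that("lattice entropy rates match the engine, flow is constant", {
  sp <- lattice_rw(1.5, 0.5)
  e <- lattice_rw_entropy(sp, 1)
  expect_equal(e$se, -(1.5 - 0.5) * log(3), tolerance = 1e-14)
  W <- lattice_rw_chain(sp, 60)
  er <- entropy_rates(solve_master(W, as.numeric(-60:60 == 0), 1)[1, ], W, pi = NA)
  expect_equal(e$si, er$si, tolerance = 1e-8)
  expect_equal(e$se, er$se, tolerance = 1e-8)
  # t = 0 divergence is flagged, not fabricated
  e0 <- lattice_rw_entropy(sp, 0)
  expect_identical(e0$si, Inf)
  expect_true("divergent_at_t0" %in% e0$flags)
})

test_that("lattice entropy production approaches the stated asymptotes", {
  # symmetric walk: t * si -> 1/2 with O(1/t^2) error
  es <- lattice_rw_entropy(lattice_rw(1, 1), 50)
  expect_equal(50 * es$si, 0.5, tolerance = 1e-3)
  # biased walk: si - (r-l) ln(r/l) - 1/(2t) -> 0
  sp <- lattice_rw(1.5, 0.5)
  for (t in c(20, 40)) {
    e <- lattice_rw_entropy(sp, t)
    expect_equal(e$si, lattice_rw_si_asymptote(sp, t), tolerance = 1e-3)
  }
})

test_that("lattice walk converges to drift-diffusion in the continuum limit", {
  v <- 1; D <- 1; t <- 1
  spD <- diffusion_spec(v = v, D = D)
  xg <- seq(-4, 6, by = 0.5)
  sup_err <- vapply(c(0.5, 0.25, 0.125), function(a) {
    r <- D / a^2 + v / (2 * a)
    l <- D / a^2 - v / (2 * a)
    sp <- lattice_rw(r, l, a = a)
    max(abs(lattice_rw_density(sp, xg, t) / a - dd_density_current(spD, xg, t)$P))
  }, numeric(1))
  expect_true(all(diff(sup_err) < 0))    # error shrinks with the spacing
  expect_lt(sup_err[3], 5e-3)
})

test_that("ring walk density wraps the lattice solution (cyclic-chain oracle)", {
  sp <- ring_rw(2, 1, L = 5)
  W <- ring_rw_chain(sp)
  p0 <- as.numeric(ring_rw_density(sp, 0))
  expect_equal(sum(p0), 1)
  for (t in c(0.3, 0.7, 2)) {
    tr <- solve_master(W, p0, t)
    expect_close(ring_rw_density(sp, t), tr[1, ], 1e-10)
  }
})

test_that("ring walk entropy rates match the engine and the stationary law", {
  sp <- ring_rw(2, 1, L = 5)
  W <- ring_rw_chain(sp)
  p0 <- as.numeric(ring_rw_density(sp, 0))
  sol <- ring_rw_solution(sp, 0.7)
  er <- entropy_rates(solve_master(W, p0, 0.7)[1, ], W, pi = NA)
  expect_equal(sol$si, er$si, tolerance = 1e-9)
  expect_equal(sol$se, er$se, tolerance = 1e-9)
  # stationary production (r - l) ln(r/l), independent of the ring size
  for (L in c(4, 5, 8)) {
    late <- ring_rw_solution(ring_rw(2, 1, L = L), 100)
    expect_equal(late$si, log(2), tolerance = 1e-10)
  }
  # total entropy rate si + se -> 0 at stationarity
  late <- ring_rw_solution(sp, 100)
  expect_equal(late$si + late$se, 0, tolerance = 1e-10)
  # symmetric rates: equilibrium ring
  expect_equal(ring_rw_solution(ring_rw(1, 1, L = 5), 100)$si, 0, tolerance = 1e-10)
})

test_that("two-site rings are rejected with a pointer to the two-state system", {
  expect_error(ring_rw(1, 1, L = 2), "two_state")
  expect_error(ring_rw(1, 1, L = 2.5), "multiple of a")
})
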