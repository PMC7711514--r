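grid_around <- function(center, sd, n = 3001, w = 10) {
  seq(center - w * sd, center + w * sd, length.out = n)
}

test_that("drift-diffusion density and current have the stated structure", {
  sp <- diffusion_spec(v = 0, D = 1)
  f <- dd_density_current(sp, grid_around(0, sqrt(2)), 1)
  h <- f$x[2] - f$x[1]
  expect_equal(sum(f$P) * h, 1, tolerance = 1e-8)
  # no drift: current is odd around the start, zero at x0
  expect_equal(stats::approx(f$x, f$j, xout = 0)$y, 0, tolerance = 1e-12)

  spv <- diffusion_spec(v = 1, D = 1)
  fv <- dd_density_current(spv, grid_around(1, sqrt(2)), 1)
  ce <- current_entropy(fv$x, fv$P, fv$j, 1, F = rep(1, length(fv$x)))
  expect_equal(ce$si, 1 / 2 + 1, tolerance = 1e-8)   # quadrature of j^2/(DP)
  expect_equal(ce$se, -1, tolerance = 1e-8)          # -v^2/D from -mu/D int F j
  expect_error(dd_density_current(spv, 0, 0), "t > 0")
})

test_that("dd_entropy matches the closed form 1/(2t) + v^2/D", {
  expect_equal(dd_entropy(diffusion_spec(v = 0, D = 1), 5)$si, 0.1)
  expect_equal(dd_entropy(diffusion_spec(v = 1, D = 1), 1e6)$si, 1, tolerance = 1e-6)
  e <- dd_entropy(diffusion_spec(v = 2, D = 0.5), c(0.5, 2))
  expect_equal(e$si, 1 / (2 * c(0.5, 2)) + 8)
  expect_equal(e$se, rep(-8, 2))
  expect_error(dd_entropy(diffusion_spec(v = 1, D = 1), 0), "t > 0")
})

test_that("driven harmonic confinement: closed forms, quadrature oracle, equilibration", {
  sp <- diffusion_spec(v = 1, D = 1, k = 1, x0 = 0)
  s <- ou_solution(sp, 0.7)
  xg <- grid_around(s$mean, sqrt(s$var), n = 4001)
  f <- ou_solution(sp, 0.7, x = xg)$fields
  ce <- current_entropy(f$x, f$P, f$j, sp$D, F = sp$v - sp$k * f$x)
  expect_equal(ce$si, s$si, tolerance = 1e-8)
  expect_equal(ce$se, s$se, tolerance = 1e-8)
  # long-time limit: equilibrium in the effective potential
  s20 <- ou_solution(sp, 20)
  expect_lt(abs(s20$si), 1e-8)
  expect_lt(abs(s20$se), 1e-8)
  expect_equal(s20$mean, sp$v / sp$k, tolerance = 1e-6)
  expect_equal(s20$var, sp$D / sp$k, tolerance = 1e-6)
  # started at the stationary mean: only the variance transient remains
  spm <- diffusion_spec(v = 2, D = 1, k = 2, x0 = 1)
  sm <- ou_solution(spm, 0.5)
  kk <- spm$k
  expect_equal(sm$si, -kk * exp(-2 * kk * 0.5) +
                 kk * exp(-2 * kk * 0.5) / (1 - exp(-2 * kk * 0.5)),
               tolerance = 1e-12)
  # k = 0 falls back to free drift-diffusion
  s0 <- ou_solution(diffusion_spec(v = 1, D = 1, k = 0), 2)
  expect_equal(s0$si, dd_entropy(diffusion_spec(v = 1, D = 1), 2)$si)
})

test_that("ring diffusion: flat potential and equilibrium limits", {
  sp0 <- diffusion_spec(v = 1, D = 1, domain = "ring", L = 1)
  r0 <- ring_stationary(sp0)
  expect_close(r0$Ps, rep(1, sp0$ng), 1e-10)
  expect_equal(r0$j, 1, tolerance = 1e-10)
  expect_equal(r0$si, 1, tolerance = 1e-10)
  expect_equal(r0$se, -1, tolerance = 1e-10)
  # no drive: equilibrium in any potential
  rv <- ring_stationary(diffusion_spec(v = 0, D = 1, domain = "ring", L = 1,
                                       V = function(x) 0.3 * cos(2 * pi * x)))
  expect_equal(rv$j, 0, tolerance = 1e-14)
  expect_equal(rv$si, 0, tolerance = 1e-12)
})

test_that("ring diffusion: the two printed routes to the stationary rates agree", {
  sp <- diffusion_spec(v = 1, D = 1, domain = "ring", L = 1,
                       V = function(x) 0.3 * cos(2 * pi * x))
  r <- ring_stationary(sp)
  # si from int j^2/(D Ps) vs -se from the current route
  expect_equal(r$si, -r$se, tolerance = 1e-8)
  # and against the generic field quadrature with the spectral force
  fe <- ring_field_entropy(sp, r$Ps, rep(r$j, sp$ng))
  expect_equal(fe$si, r$si, tolerance = 1e-8)
  expect_equal(fe$se, r$se, tolerance = 1e-6)
})

test_that("stationary ring current is extremal for a constant potential", {
  set.seed(5)
  sp0 <- diffusion_spec(v = 1, D = 1, domain = "ring", L = 1)
  j0 <- abs(ring_stationary(sp0)$j)
  for (i in 1:6) {
    amp <- stats::runif(2, 0.05, 0.5)
    ph <- stats::runif(2, 0, 2 * pi)
    V <- function(x) amp[1] * cos(2 * pi * x + ph[1]) +
      amp[2] * sin(4 * pi * x + ph[2])
    jV <- abs(ring_stationary(diffusion_spec(v = 1, D = 1, domain = "ring",
                                             L = 1, V = V))$j)
    expect_lt(jV, j0)
  }
})

test_that("current_entropy flags a divergent current instead of clamping", {
  x <- seq(0, 1, length.out = 11)
  P <- rep(0.1, 11); P[5] <- 0
  j <- rep(1, 11)
  ce <- current_entropy(x, P, j, D = 1)
  expect_identical(ce$si, Inf)
  expect_true("divergent_current" %in% ce$flags)
  expect_equal(attr(ce$flags, "locations"), x[5])
})

test_that("diffusion_spec validates its inputs", {
  expect_error(diffusion_spec(D = 0), "D > 0")
  expect_error(diffusion_spec(domain = "ring"), "circumference")
  expect_error(diffusion_spec(domain = "ring", L = 1,
                              V = function(x) x), "periodic")
})
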