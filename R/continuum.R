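#' One-dimensional diffusion specification
#'
#' Overdamped Langevin dynamics \eqn{\dot x = \mu F(x) + \zeta(t)} with
#' noise covariance \eqn{2 D \delta(t - t')}; mobility is fixed to
#' \eqn{\mu = 1} so the bath temperature is \eqn{T = D}. Covered forces:
#' constant drift `v` (free drift-diffusion on the line), an additional
#' harmonic restoring force `-k x` (driven Ornstein-Uhlenbeck), or a
#' periodic potential `V` on a ring of circumference `L`.
#'
#' @param v constant drift (length/time).
#' @param D diffusion constant (length^2/time), positive.
#' @param k harmonic stiffness (1/time), non-negative; `k > 0` selects the
#'   harmonic (Ornstein-Uhlenbeck) system on the line.
#' @param domain `"line"` or `"ring"`.
#' @param L ring circumference (required for `domain = "ring"`).
#' @param x0 initial position (point initial condition).
#' @param V periodic potential for the ring: either a function of x
#'   (vectorised, period `L`) or a numeric vector sampling `V` on the
#'   uniform grid `seq(0, L, length.out = ng + 1)[-(ng+1)]`.
#' @param ng number of spatial grid points for quadrature (>= 64).
#' @return object of class `"diffusion_spec"`.
#' @export
diffusion_spec <- function(v = 0, D = 1, k = 0, domain = c("line", "ring"),
                           L = NULL, x0 = 0, V = NULL, ng = 512) {
  domain <- match.arg(domain)
  stopifnot(D > 0, k >= 0, ng >= 64)
  if (domain == "ring") {
    if (is.null(L) || L <= 0) stop("ring domain needs a positive circumference L")
    if (k > 0) stop("harmonic confinement is a line-domain system")
  }
  Vgrid <- NULL
  if (!is.null(V)) {
    if (domain != "ring") stop("a sampled potential is only supported on the ring")
    x <- ring_grid(L, ng)
    if (is.function(V)) {
      Vgrid <- V(x)
      if (abs(V(0) - V(L)) > 1e-12 * max(1, abs(V(0)))) {
        stop("potential must be periodic: V(0) must equal V(L)")
      }
    } else {
      if (length(V) != ng) stop("sampled potential must have length ng")
      Vgrid <- as.numeric(V)
    }
  }
  structure(list(v = v, D = D, k = k, domain = domain, L = L, x0 = x0,
                 V = V, Vgrid = Vgrid, ng = ng, mu = 1, temperature = D),
            class = "diffusion_spec")
}

ring_grid <- function(L, ng) seq(0, L, length.out = ng + 1L)[-(ng + 1L)]

#' Density and current of free drift-diffusion on the line
#'
#' From a point start at `x0` the density is the spreading Gaussian
#' \eqn{P(x,t) = (4\pi D t)^{-1/2} e^{-(x - x_0 - v t)^2 / 4 D t}} and the
#' current is \eqn{j = (v - D\partial_x) P = [v/2 + (x - x_0 - v t)/2t +
#' v/2] P}, i.e. `j = (v + (x - x0 - v t)/(2 t)) * P`.
#'
#' @param spec a [diffusion_spec()] with `k = 0`, line domain.
#' @param x positions; vectorised.
#' @param t a single positive time.
#' @return data frame with columns `x`, `P`, `j`.
#' @export
dd_density_current <- function(spec, x, t) {
  stopifnot(inherits(spec, "diffusion_spec"), spec$domain == "line",
            spec$k == 0, length(t) == 1L)
  if (t <= 0) stop("density requires t > 0 (point mass at t = 0)")
  v <- spec$v; D <- spec$D
  u <- x - spec$x0 - v * t
  P <- exp(-u^2 / (4 * D * t)) / sqrt(4 * pi * D * t)
  j <- (v + u / (2 * t)) * P
  data.frame(x = x, P = P, j = j)
}

#' Entropy rates of free drift-diffusion
#'
#' \eqn{\dot S_i(t) = 1/(2t) + v^2/D}, \eqn{\dot S_e = -v^2/D}. The
#' transient `1/(2t)` is independent of all parameters; the `v^2/D` part
#' persists indefinitely because the spreading packet never reaches a
#' stationary density.
#'
#' @inheritParams dd_density_current
#' @param t positive time(s); vectorised.
#' @return data frame with columns `t`, `si`, `se`.
#' @export
dd_entropy <- function(spec, t) {
  stopifnot(inherits(spec, "diffusion_spec"), spec$k == 0)
  if (any(t <= 0)) stop("entropy rates require t > 0")
  data.frame(t = t, si = 1 / (2 * t) + spec$v^2 / spec$D,
             se = rep(-spec$v^2 / spec$D, length(t)))
}

#' Driven Ornstein-Uhlenbeck process: density, current, entropy rates
#'
#' Drift-diffusion in a harmonic potential \eqn{V(x) = k x^2/2},
#' \eqn{\dot x = v - k x + \sqrt{2D}\xi}. From a point start the density
#' stays Gaussian with mean \eqn{m(t) = x_0 e^{-kt} + (v/k)(1 - e^{-kt})}
#' and variance \eqn{\sigma^2(t) = (D/k)(1 - e^{-2kt})}. The entropy
#' rates are
#' \deqn{\dot S_i(t) = \left[\frac{(v - k x_0)^2}{D} - k\right]e^{-2kt}
#'       + \frac{k e^{-2kt}}{1 - e^{-2kt}}, \qquad
#'       \dot S_e(t) = -\left[\frac{(v - k x_0)^2}{D} - k\right]e^{-2kt};}
#' both vanish as \eqn{t \to \infty} when the density settles into the
#' Boltzmann form of the effective potential \eqn{k x^2/2 - v x}: the
#' confined system equilibrates.
#'
#' @param spec a [diffusion_spec()] with `k > 0` (with `k = 0` the free
#'   drift-diffusion formulas apply, see [dd_entropy()]).
#' @param t a single positive time.
#' @param x optional positions at which to evaluate density and current.
#' @return list with `mean`, `var`, `si`, `se`, and (when `x` is given) a
#'   data frame `fields` with columns `x`, `P`, `j`.
#' @export
ou_solution <- function(spec, t, x = NULL) {
  stopifnot(inherits(spec, "diffusion_spec"), spec$domain == "line",
            length(t) == 1L, t > 0)
  v <- spec$v; D <- spec$D; k <- spec$k; x0 <- spec$x0
  if (k <= 0) {
    out <- dd_entropy(spec, t)
    res <- list(mean = x0 + v * t, var = 2 * D * t, si = out$si, se = out$se)
    if (!is.null(x)) res$fields <- dd_density_current(spec, x, t)
    return(res)
  }
  e1 <- exp(-k * t); e2 <- exp(-2 * k * t)
  m <- x0 * e1 + (v / k) * (1 - e1)
  s2 <- (D / k) * (1 - e2)
  si <- ((v - k * x0)^2 / D - k) * e2 + k * e2 / (1 - e2)
  se <- -((v - k * x0)^2 / D - k) * e2
  res <- list(mean = m, var = s2, si = si, se = se)
  if (!is.null(x)) {
    P <- stats::dnorm(x, m, sqrt(s2))
    # j = (v - k x) P - D dP/dx, with dP/dx = -(x - m)/s2 * P
    j <- ((v - k * x) + D * (x - m) / s2) * P
    res$fields <- data.frame(x = x, P = P, j = j)
  }
  res
}

#' Entropy rates from density and current fields
#'
#' Direct quadrature of
#' \eqn{\dot S_i = \int j^2 / (D P)\, dx \ge 0} and
#' \eqn{\dot S_e = -(\mu/D)\int F j \, dx}. Works for any fields sampled
#' on a common grid; on a ring the grid is treated as periodic
#' (rectangle rule), on the line the trapezoid rule is used and the
#' fields must decay within the grid.
#'
#' @param x spatial grid (uniform).
#' @param P density samples (non-negative, normalised on the grid).
#' @param j current samples.
#' @param D diffusion constant.
#' @param F force samples (only needed for `se`).
#' @param mu mobility (default 1).
#' @param periodic treat the grid as one period of a ring.
#' @return list with `si`, `se` (`se = NA` without `F`), and `flags`
#'   (reports `"divergent_current"` with the offending locations when
#'   `P = 0` where `j != 0`).
#' @export
current_entropy <- function(x, P, j, D, F = NULL, mu = 1, periodic = FALSE) {
  stopifnot(length(x) == length(P), length(x) == length(j), D > 0)
  flags <- character(0)
  bad <- which(P <= 0 & j != 0)
  if (length(bad)) {
    flags <- "divergent_current"
    attr(flags, "locations") <- x[bad]
    si <- Inf
  } else {
    integrand <- ifelse(P > 0, j^2 / (D * P), 0)
    si <- quad_grid(x, integrand, periodic)
  }
  se <- NA_real_
  if (!is.null(F)) se <- -quad_grid(x, (mu / D) * F * j, periodic)
  list(si = si, se = se, flags = flags)
}

quad_grid <- function(x, y, periodic = FALSE) {
  h <- x[2] - x[1]
  if (periodic) return(h * sum(y))
  h * (sum(y) - (y[1] + y[length(y)]) / 2)
}
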