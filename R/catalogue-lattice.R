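#' Biased random walk on the one-dimensional lattice
#'
#' Specification of a continuous-time nearest-neighbour walk: hop right
#' with rate `r`, left with rate `l`, lattice spacing `a`, started at
#' `x0`. The asymmetric case `r != l` is the minimal model of a molecular
#' motor stepping along a filament. Positions are handled internally as
#' integer site offsets from `x0` to avoid float-parity errors.
#'
#' @param r right-hopping rate (> 0).
#' @param l left-hopping rate (> 0).
#' @param a lattice spacing (> 0).
#' @param x0 initial position.
#' @return object of class `"lattice_rw"`.
#' @export
lattice_rw <- function(r, l, a = 1, x0 = 0) {
  stopifnot(r > 0, l > 0, a > 0)
  structure(list(r = r, l = l, a = a, x0 = x0), class = "lattice_rw")
}

site_offsets <- function(spec, x) {
  m <- (x - spec$x0) / spec$a
  if (any(abs(m - round(m)) > 1e-9)) {
    stop("positions must lie on the lattice x0 + a * Z")
  }
  as.integer(round(m))
}

# probability of a site offset m at time t: exp(-(l+r)t) (r/l)^(m/2) I_|m|(2t sqrt(rl)),
# evaluated with exponentially scaled Bessel functions for stability
lattice_site_prob <- function(r, l, t, m) {
  z <- 2 * t * sqrt(r * l)
  logp <- (z - (l + r) * t) + (m / 2) * log(r / l) +
    log(besselI(z, abs(m), expon.scaled = TRUE))
  exp(logp)
}

#' Occupation probability of the lattice walk
#'
#' Closed form via the modified Bessel function of the first kind:
#' \deqn{P(x, t; x_0) = e^{-(\ell + r) t}
#'   (r/\ell)^{\frac{x - x_0}{2a}}
#'   I_{|x - x_0|/a}\!\big(2 t \sqrt{r \ell}\big).}
#'
#' @param spec a [lattice_rw()].
#' @param x positions (must be lattice points `x0 + a * Z`); vectorised.
#' @param t a single non-negative time.
#' @return vector of probabilities.
#' @export
lattice_rw_density <- function(spec, x, t) {
  stopifnot(inherits(spec, "lattice_rw"), length(t) == 1L, t >= 0)
  m <- site_offsets(spec, x)
  if (t == 0) return(as.numeric(m == 0L))
  lattice_site_prob(spec$r, spec$l, t, m)
}

# symmetric site range capturing all but ~1e-16 of the mass at time t
lattice_site_range <- function(r, l, t, pad = 10L) {
  drift <- (r - l) * t
  width <- 12 * sqrt((r + l) * t) + pad
  c(floor(drift - width), ceiling(drift + width))
}

#' Entropy rates of the lattice random walk
#'
#' The entropy flow is position-independent and constant,
#' \eqn{\dot S_e = -(r - \ell)\ln(r/\ell)}. The internal entropy
#' production is the Bessel-function series
#' \deqn{\dot S_i(t) = \tfrac12 (r-\ell)\ln\frac{r}{\ell}
#'  + e^{-(\ell+r)t}\sum_m (r/\ell)^{m/2} I_{|m|}(z)
#'  \left[r \ln\frac{I_{|m|}(z)}{I_{|m+1|}(z)}
#'  + \ell \ln\frac{I_{|m|}(z)}{I_{|m-1|}(z)}\right]}
#' with \eqn{z = 2t\sqrt{r\ell}}. The sum is truncated adaptively: terms
#' are accumulated over a window around the drifted centre of mass that is
#' widened until the boundary terms fall below `1e-15` of the partial sum
#' (the series mixes growing and decaying factors, so a fixed cutoff is
#' unsafe). On the infinite lattice the Shannon entropy itself never
#' converges; no claim is made about \eqn{\lim_{t\to\infty}\dot S}.
#'
#' @inheritParams lattice_rw_density
#' @param t a single positive time (the rate diverges at `t = 0`).
#' @return list with `si`, `se`, and `terms` (number of lattice sites
#'   summed over).
#' @export
lattice_rw_entropy <- function(spec, t) {
  stopifnot(inherits(spec, "lattice_rw"), length(t) == 1L)
  r <- spec$r; l <- spec$l
  se <- -(r - l) * log(r / l)
  if (t <= 0) {
    return(list(si = Inf, se = se, terms = 0L,
                flags = "divergent_at_t0"))
  }
  z <- 2 * t * sqrt(r * l)
  rng <- lattice_site_range(r, l, t)
  repeat {
    m <- rng[1]:rng[2]
    logI <- log(besselI(z, abs(m), expon.scaled = TRUE))
    logIp <- log(besselI(z, abs(m + 1), expon.scaled = TRUE))
    logIm <- log(besselI(z, abs(m - 1), expon.scaled = TRUE))
    P <- lattice_site_prob(r, l, t, m)
    term <- P * (r * (logI - logIp) + l * (logI - logIm))
    term[!is.finite(term) & P == 0] <- 0
    tot <- sum(term)
    edge <- max(abs(term[1]), abs(term[length(term)]))
    if (edge <= 1e-15 * max(abs(tot), 1e-300) || diff(rng) > 1e6) break
    rng <- rng + c(-50L, 50L)
  }
  si <- 0.5 * (r - l) * log(r / l) + tot
  list(si = si, se = se, terms = length(m))
}

#' Large-time asymptote of the lattice-walk entropy production
#'
#' \eqn{(r-\ell)\ln(r/\ell) + 1/(2t)} for biased walks and
#' \eqn{1/(2t)} for the symmetric walk.
#'
#' @inheritParams lattice_rw_entropy
#' @return asymptotic \eqn{\dot S_i(t)}.
#' @export
lattice_rw_si_asymptote <- function(spec, t) {
  with(spec, if (r == l) 1 / (2 * t) else (r - l) * log(r / l) + 1 / (2 * t))
}

#' Truncated-lattice rate matrix
#'
#' Finite nearest-neighbour chain on sites `-M..M` (used as the generic
#' master-equation cross-check of the closed forms; the truncation must be
#' wide enough that no probability reaches the boundary).
#'
#' @inheritParams lattice_rw_density
#' @param M half-width in sites.
#' @return a [rate_matrix()] on `2M + 1` states labelled by site offset.
#' @export
lattice_rw_chain <- function(spec, M) {
  d <- 2L * M + 1L
  w <- matrix(0, d, d)
  for (i in seq_len(d - 1L)) {
    w[i, i + 1L] <- spec$r
    w[i + 1L, i] <- spec$l
  }
  rate_matrix(w, labels = as.character(-M:M))
}

#' Biased random walk on a ring lattice
#'
#' The walk of [lattice_rw()] wrapped onto a ring of `L / a >= 3` sites.
#' Rings of two sites have a different transition topology (both hops
#' connect the same pair of states and their entropy productions are not
#' additive); use the two-state process instead.
#'
#' @inheritParams lattice_rw
#' @param L ring circumference (an integer multiple of `a`).
#' @return object of class `"ring_rw"`.
#' @export
ring_rw <- function(r, l, L, a = 1, x0 = a) {
  stopifnot(r > 0, l > 0, a > 0)
  nsites <- L / a
  if (abs(nsites - round(nsites)) > 1e-9) stop("L must be a multiple of a")
  nsites <- as.integer(round(nsites))
  if (nsites < 3L) {
    stop(structure(
      class = c("entroprod_unsupported_topology", "error", "condition"),
      list(message = paste(
        "ring lattices need L/a >= 3 sites; the two-site ring has a",
        "different transition topology -- use two_state_solution() with",
        "alpha = beta = r + l"), call = sys.call(-1))))
  }
  structure(list(r = r, l = l, a = a, L = L, nsites = nsites, x0 = x0),
            class = "ring_rw")
}

#' Occupation probabilities on the ring lattice
#'
#' Wrapped (winding-number) sum of the infinite-lattice density,
#' \eqn{P_L(x, t) = \sum_j P(x + j L, t; x_0)}, truncated once the
#' Gaussian tail of the jump-count distribution is below `1e-14`.
#'
#' @param spec a [ring_rw()].
#' @param t a single non-negative time.
#' @return vector of site probabilities for sites `x = a, 2a, ..., L`.
#' @export
ring_rw_density <- function(spec, t) {
  stopifnot(inherits(spec, "ring_rw"), length(t) == 1L, t >= 0)
  ns <- spec$nsites
  sites <- seq_len(ns) * spec$a
  m0 <- site_offsets(lattice_rw(spec$r, spec$l, spec$a, spec$x0), sites)
  if (t == 0) return(as.numeric(m0 %% ns == 0L))
  rng <- lattice_site_range(spec$r, spec$l, t)
  jmax <- ceiling(max(abs(rng)) / ns) + 1L
  P <- rep(0, ns)
  for (j in -jmax:jmax) {
    P <- P + lattice_site_prob(spec$r, spec$l, t, m0 + j * ns)
  }
  P / sum(P)
}

#' Entropy rates of the random walk on a ring lattice
#'
#' \deqn{\dot S_i(t) = (r-\ell)\ln\frac{r}{\ell} + \sum_{m=1}^{L/a}
#'   P_L(ma, t)\left[r \ln\frac{P_L(ma,t)}{P_L((m{+}1)a,t)} +
#'   \ell \ln\frac{P_L(ma,t)}{P_L((m{-}1)a,t)}\right]}
#' with \eqn{\dot S_e = -(r-\ell)\ln(r/\ell)} as on the line. At
#' stationarity the distribution is uniform, the bracket vanishes and
#' \eqn{\dot S_i \to (r-\ell)\ln(r/\ell)}, independent of the ring size:
#' a non-equilibrium steady state for any `r != l`.
#'
#' @inheritParams ring_rw_density
#' @return list with `si`, `se`, `si_stationary` and the site
#'   probabilities `P`.
#' @export
ring_rw_solution <- function(spec, t) {
  r <- spec$r; l <- spec$l
  P <- ring_rw_density(spec, t)
  fw <- c(P[-1], P[1])   # P at site m+1
  bw <- c(P[spec$nsites], P[-spec$nsites])
  term <- function(Pa, Pb, rate) {
    ifelse(Pa > 0 & Pb > 0, rate * Pa * log(Pa / Pb),
           ifelse(Pa == 0, 0, Inf))
  }
  si <- (r - l) * log(r / l) + sum(term(P, fw, r) + term(P, bw, l))
  list(si = si, se = -(r - l) * log(r / l),
       si_stationary = (r - l) * log(r / l), P = P)
}

#' Ring-lattice rate matrix
#' @inheritParams ring_rw_density
#' @return the `L/a`-state cyclic [rate_matrix()] of the ring walk.
#' @export
ring_rw_chain <- function(spec) {
  cyclic_rate_matrix(spec$nsites, spec$r, spec$l)
}
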