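---
title: "Entropy production in exactly solvable stochastic processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy production in exactly solvable stochastic processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entroprod)
```

## Scope and model

`entroprod` computes entropy production rates for Markovian dynamics in
three settings: discrete-state jump processes (continuous-time Markov
chains), one-dimensional diffusions, and mixed discrete–continuous
processes (diffusion with stochastic drift switching). Throughout,
entropy is measured in nats with $k_B = 1$, the mobility is fixed at
$\mu = 1$ (so the bath temperature is $T = D$), and all transition rates
are time independent. The dimensional scale constants that appear inside
logarithms of rates or densities cancel identically in every rate
computed here and are fixed to one.

For a chain with rates $w_{nm}$ and occupation $P_n(t)$, the package
evaluates the decomposition of the Shannon entropy rate
$$\dot S = \dot S_i + \dot S_e, \qquad
\dot S_i = \tfrac12\sum_{n,m}\left(P_n w_{nm} - P_m w_{mn}\right)
\ln\frac{P_n w_{nm}}{P_m w_{mn}} \ \ge 0,$$
with $\dot S_e$ carrying the factor $\ln(w_{nm}/w_{mn})$, the entropy
exported per jump to the reservoirs. The internal part splits further
into an adiabatic (housekeeping) term, evaluated with the stationary
weights, and a non-adiabatic (excess) term
$-\sum_n \dot P_n \ln(P_n/\pi_n)$ that vanishes at stationarity. For
diffusions the same decomposition is evaluated either from density and
current, $\dot S_i = \int j^2/(DP)\,dx$, or from the short-time
propagator through the time-reversal (Kullback–Leibler) route, which the
package performs numerically for user-supplied propagators.

These formulas are assumption-laden in well-defined ways: Markovianity,
time-independent generators, and (for the stationary decompositions) a
unique stationary state. The package checks the last assumption
spectrally and refuses chains with several ergodic components rather
than picking a component silently.

## Conventions for vanishing rates and probabilities

Terms with zero forward *and* backward flux are dropped
($0\ln 0 = 0$). A pair with positive forward flux but no reverse channel
makes $\dot S_i$ genuinely infinite; the package returns `Inf` with a
flag rather than clamping, and distinguishes two causes: a zero reverse
*rate* (`irreversible_transition`, absolute irreversibility of the
model) and a zero *occupation* of the target state
(`zero_probability`, typical of point-mass initial conditions at
$t = 0$, where the production rate really does diverge). The same policy
applies in the continuum: a current flowing through a region of zero
density is reported as a flagged divergence with its location.

## Numerical choices

* **Master equation.** $P(t) = P(0)e^{wt}$ via the matrix exponential
  (`Matrix::expm`), stepping incrementally along the requested grid.
  ODE integration (`deSolve`) is kept strictly as an independent oracle
  in the test suite, at tolerance $10^{-12}$.
* **Stationary states.** Left null vector of the generator by dense
  eigendecomposition; the zero eigenvalue must be simple within
  $10^{-10}$ of the spectral scale, otherwise the chain is refused.
* **Lattice-walk Bessel sums.** The entropy series of the biased lattice
  walk mixes exponentially growing Bessel factors with an overall
  exponential damping, so a fixed truncation is unsafe. Terms are
  accumulated over a window centred on the drifted mean, initially
  $12\sqrt{(r+\ell)t}$ wide, and the window grows until the edge terms
  fall below $10^{-15}$ of the partial sum. Scaled Bessel functions
  (`besselI(..., expon.scaled = TRUE)`) keep every factor in range.
  Lattice positions are integer site indices internally; physical
  positions enter only as $x_0 + m a$, which avoids float-parity bugs in
  the jump-count bookkeeping.
* **Ring-lattice wrapping.** The ring density is the winding-number sum
  of the infinite-lattice density, truncated when the Poissonian tail of
  the jump-count distribution is negligible ($10^{-14}$).
* **Ring diffusion.** Stationary density on a uniform periodic grid
  (default $N_g = 512$): periodic integrands use the rectangle rule
  (spectrally accurate for smooth potentials), while the inner
  fixed-width integral $\int_x^{x+L} e^{(V - vy)/D}dy$, whose integrand
  is not periodic, uses Simpson's rule over one unwrapped period. The
  implementation evaluates the unnormalised density as
  $e^{-V(x)/D}\int_0^L e^{(V(x+s)-vs)/D}ds$, in which the non-periodic
  $e^{\pm vx/D}$ factors cancel analytically, and obtains the uniform
  current as $j = D(1-e^{-vL/D})/Z_0$ from the periodicity condition
  — a form checked against the flat-potential limit $j = v/L$ and
  against the identity $j\int_0^L dx/P_s = vL$, which guarantees
  $\dot S_i = -\dot S_e$ at stationarity. Potential derivatives are
  spectral (FFT) when only samples are given.
* **Propagator-limit route.** $\dot S_i(\tau)$ and $\dot S_e(\tau)$ are
  double integrals evaluated on an outer grid over the density's support
  and an inner window following the propagator's drift and width; the
  $\tau \to 0$ limit is taken by first-order Richardson extrapolation
  along a geometric sequence $\tau_k = \tau_0 2^{-k}$, $k = 0..6$. The
  values are linear in $\tau$ for Gaussian propagators, so the
  extrapolation is effectively exact; the residual between successive
  extrapolants is reported, and results with residuals above tolerance
  are flagged `non_convergent` instead of returned silently.
* **Degenerate inputs.** $t = 0$ entropy rates of point starts are
  infinite and flagged; two-site rings are rejected with a pointer to
  the two-state solver (their transition topology differs: concurrent
  rates between the same pair of states are additive, their entropy
  productions are not).

## Simulators and estimators

Jump processes are sampled exactly (Gillespie: exponential waiting
times, categorical destinations). Diffusions use Euler–Maruyama with
Gaussian increments of variance $2D\,dt$; mode switching uses per-step
transition probabilities $\alpha_{ij}\,dt$. The integrator refuses
steps that do not resolve the fastest rate ($k\,dt$ or
$\max|\alpha|\,dt \ge 0.1$) and suggests a stable step. One root seed
drives a single RNG stream, so runs are bit-reproducible; seeds and
configurations are echoed into JSON sidecars by the writers.

Estimators:

* **Jump medium entropy** — each jump contributes
  $\ln(w_{nm}/w_{mn})$; the time average converges to $-\dot S_e$
  ($= \dot S_i$ at stationarity). Standard errors are over independent
  paths.
* **Path KL rate** — paths discretised at interval $\tau$; empirical
  state frequencies are combined with the exact propagator matrix
  $e^{w\tau}$ in the plug-in divergence. The estimator carries a
  downward $O(\tau)$ bias at finite sampling; the package reports the
  trend across $\tau$ rather than extrapolating, since no principled
  finite-$\tau$ correction is available.
* **Stratonovich heat** — $S_m(T) = \int F \circ dx / T$ with the force
  at the interval midpoint. The midpoint rule is load-bearing: it is
  what makes the discrete heat equal the log-ratio of forward and
  backward path weights. The Ito variant (force at the left point) is
  available behind a flag to demonstrate that it estimates a different
  quantity — for an equilibrated harmonic well it returns
  $\langle F^2\rangle/D \approx k$ instead of zero.
* **Mode-switch entropy** — jump-contribution estimator over the
  recorded mode sequence, the discrete analogue of the medium entropy.

For stationary estimates the simulations are started in the stationary
state (uniform ring positions, stationary mode weights), which removes
the need for burn-in; when a transient start is unavoidable the leading
portion of the paths should be discarded, as done in the test suite for
the harmonic well.

## What the generators emulate, and what they do not

The built-in random-matrix and path generators define the study
conditions for the tests: generic chains with i.i.d. exponential rates,
detailed-balance chains built from random state energies
($w_{nm} = r_{nm}e^{(E_n - E_m)/2}$ with symmetric $r$), driven rings,
and the catalogue systems at the parameter values used throughout
(forward/backward rates 2/1, drifts of order 1, $D = 1$, 1000–5000
paths, horizons of 10–20 inverse rates). Simulation checks pass at three
standard errors. Passing these suites demonstrates internal consistency
of the three routes (closed form, generic engine, trajectory estimators)
under Markovian, time-homogeneous dynamics with moderate state spaces.
It does not demonstrate robustness to features real trajectory data
have: measurement noise, finite sampling rates far from the rate scale,
non-Markovian memory, or interacting many-particle dynamics. The
many-particle results cover *non-interacting* particles only, where
occupation-number processes reduce to products of single-particle laws.

## Problem sizes

The test and acceptance runs use desk-scale problems chosen to keep the
whole suite fast while leaving clear margins: chains of up to ~200
occupation states for oracles, lattice truncations of ±60–80 sites
checked against mass conservation, $N_g = 512$ ring grids,
1200–5000 trajectories per estimator check. All quantitative claims in
this vignette are computed by the test suite or the acceptance script;
none are transcribed from elsewhere.

## Known limitations

* Time-dependent driving protocols are out of scope; all generators are
  time homogeneous.
* The stationary entropy production of the *infinite*-lattice biased
  walk has no closed form; the package provides the numeric asymptote
  $(r-\ell)\ln(r/\ell) + 1/(2t)$ and makes no claim about
  $\lim_{t\to\infty}\dot S$ there (the Shannon entropy itself does not
  converge).
* For switching diffusion only stationary rates are computed
  analytically; time-dependent behaviour is accessible through the
  simulator.
* The Euler–Maruyama integrator does not support external potentials on
  the ring (the analytic stationary solver does); combining potentials
  with mode switching is undefined in this framework and not offered.
* Estimation from externally supplied (experimental) trajectories is
  not supported; estimators consume paths produced by the package's own
  samplers, whose discretisation they know.
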