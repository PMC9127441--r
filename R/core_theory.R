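## Equilibrium building blocks of the Poisson random field model:
## fixation probability and rate of the Wright-Fisher diffusion with genic
## selection, the equilibrium site-frequency intensity, and the equilibrium
## spectrum functional.  All quantities are parameterized by the
## population-scaled selection coefficient gamma (relative to the reference
## size N) and the size ratio kappa, and depend on them only through the
## product 2*gamma*kappa.

#' Selection regime
#'
#' Bundles the population-scaled selection coefficient `gamma` (negative for
#' deleterious mutations; scaled by the reference population size) with the
#' population size ratio `kappa` of the epoch in which the allele evolves.
#'
#' @param gamma finite numeric scalar, the scaled selection coefficient.
#' @param kappa positive numeric scalar, ratio of current to reference size.
#' @return An object of class `selection_regime`.
#' @examples
#' selection_regime(-1, 1)
#' @export
selection_regime <- function(gamma, kappa = 1) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            is.numeric(kappa), length(kappa) == 1L, is.finite(kappa))
  if (kappa <= 0) stop("'kappa' must be > 0")
  structure(list(gamma = gamma, kappa = kappa), class = "selection_regime")
}

#' @export
print.selection_regime <- function(x, ...) {
  cat(sprintf("Selection regime: gamma = %g, kappa = %g (2*gamma*kappa = %g)\n",
              x$gamma, x$kappa, 2 * x$gamma * x$kappa))
  invisible(x)
}

as_regime <- function(x, kappa = NULL) {
  if (inherits(x, "selection_regime")) {
    if (!is.null(kappa)) x$kappa <- kappa
    return(x)
  }
  selection_regime(as.numeric(x), if (is.null(kappa)) 1 else kappa)
}

#' Model parameters
#'
#' Global parameters of the mutation process and the time window: the
#' population mutation intensity `theta` per generation in the reference
#' population, the reference haploid size `N`, the time of the size change
#' `tstar` and the present time `t_present` (both in units of N generations),
#' and optionally the number of independent sites `L` (only needed to report
#' a per-site mutation rate mu = theta / (L * N)).
#'
#' @param theta positive scalar, population mutation intensity.
#' @param N reference haploid population size (>= 2).
#' @param tstar time of the size change, in units of N generations.
#' @param t_present present time, same units; must be >= `tstar`.
#' @param L optional positive number of independent sites.
#' @return An object of class `model_params`.
#' @export
model_params <- function(theta = 1, N = 1000, tstar = 1, t_present = 20, L = NULL) {
  stopifnot(theta > 0, N >= 2, tstar >= 0, t_present >= tstar)
  if (!is.null(L)) stopifnot(L > 0)
  structure(list(theta = theta, N = N, tstar = tstar,
                 t_present = t_present, L = L),
            class = "model_params")
}

## threshold below which |2*gamma*kappa| is treated as neutral
.NEUTRAL_EPS <- 1e-8

#' Fixation probability of a derived allele
#'
#' Probability that a derived allele at frequency `y`, evolving under the
#' Wright-Fisher diffusion with scaled selection `gamma` in a population of
#' size `kappa * N`, eventually reaches fixation:
#' \deqn{q_{\gamma,\kappa}(y) = \frac{1 - e^{-2\gamma\kappa y}}{1 - e^{-2\gamma\kappa}},}
#' with the neutral limit \eqn{q_{0,\kappa}(y) = y}.  Evaluation is
#' overflow-free for \eqn{|2\gamma\kappa|} into the thousands: for negative
#' selection the expression is rearranged so that all exponentials have
#' non-positive arguments.
#'
#' @param y frequency (vector) in \[0, 1\].
#' @param regime a [selection_regime], or a numeric `gamma` (then `kappa`
#'   applies).
#' @param kappa size ratio used when `regime` is numeric.
#' @return Fixation probabilities in \[0, 1\], same length as `y`.
#' @examples
#' fixation_prob(0.5, selection_regime(-1, 1))  # (1 - e) / (1 - e^2)
#' @export
fixation_prob <- function(y, regime, kappa = 1) {
  regime <- as_regime(regime, if (missing(kappa)) NULL else kappa)
  if (any(!is.finite(y)) || any(y < 0) || any(y > 1)) {
    stop("'y' must lie in [0, 1]")
  }
  x <- 2 * regime$gamma * regime$kappa
  if (abs(x) < .NEUTRAL_EPS) return(y)
  if (x < 0) {
    ## multiply numerator and denominator by e^x: all exponents <= 0
    (exp(x * (1 - y)) - exp(x)) / (-expm1(x))
  } else {
    expm1(-x * y) / expm1(-x)
  }
}

#' Instantaneous fixation rate relative to neutral
#'
#' Scaled rate at which new mutations of a selected class reach fixation in
#' an equilibrium population of size `kappa * N`, relative to the neutral
#' rate:
#' \deqn{\omega_{\gamma,\kappa} = \frac{2\gamma\kappa}{1 - e^{-2\gamma\kappa}},}
#' with \eqn{\omega_{0,\kappa} = 1}.  Depends on `gamma` and `kappa` only
#' through their product.  For strongly deleterious classes the value decays
#' to zero without overflow.
#'
#' @inheritParams fixation_prob
#' @return Positive scalar rate.
#' @examples
#' fixation_rate(selection_regime(-1, 1))  # 2 / (e^2 - 1)
#' @export
fixation_rate <- function(regime, kappa = 1) {
  regime <- as_regime(regime, if (missing(kappa)) NULL else kappa)
  x <- 2 * regime$gamma * regime$kappa
  omega_from_x(x)
}

## omega as a function of x = 2 * gamma * kappa (vectorized, stable)
omega_from_x <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  ## series keeps continuity at gamma -> 0 to ~1e-17
  out[small] <- 1 + x[small] / 2 + x[small]^2 / 12
  neg <- !small & x < 0
  out[neg] <- x[neg] * exp(x[neg]) / expm1(x[neg])
  pos <- !small & x > 0
  out[pos] <- x[pos] / (-expm1(-x[pos]))
  out
}

#' Equilibrium site-frequency intensity density
#'
#' Density of the Poisson intensity measure of segregating derived-allele
#' frequencies at equilibrium in a population of size `kappa * N`:
#' \deqn{\psi_{\gamma,\kappa}(y) = \frac{1 - e^{-2\gamma\kappa(1-y)}}{\gamma\, y (1-y)},}
#' with the neutral limit \eqn{\psi_{0,\kappa}(y) = 2\kappa / y}.  The
#' expected number of segregating sites with frequency in `dy` is
#' \eqn{\theta\, \omega_{\gamma,\kappa} \psi_{\gamma,\kappa}(y)\, dy};
#' see [sfs_intensity()] for the product, which is the numerically robust
#' object for strongly negative selection.
#'
#' @param y frequency (vector) in the open interval (0, 1).
#' @inheritParams fixation_prob
#' @return Positive density values.
#' @examples
#' sfs_density(0.5, selection_regime(0, 2))   # 2 * kappa / y = 8
#' @export
sfs_density <- function(y, regime, kappa = 1) {
  regime <- as_regime(regime, if (missing(kappa)) NULL else kappa)
  if (any(!is.finite(y)) || any(y <= 0) || any(y >= 1)) {
    stop("'y' must lie in (0, 1)")
  }
  x <- 2 * regime$gamma * regime$kappa
  if (abs(x) < .NEUTRAL_EPS) return(2 * regime$kappa / y)
  w <- -x * (1 - y)  # >= 0 for deleterious mutations
  num <- -expm1(w)   # 1 - e^{-x(1-y)}
  ifelse(is.finite(num),
         num / (regime$gamma * y * (1 - y)),
         exp(w - log(abs(regime$gamma) * y * (1 - y))))
}

## q_{gamma,kappa}(y) / y, stable down to y = 0 where it tends to omega.
q_over_y <- function(y, regime) {
  x <- 2 * regime$gamma * regime$kappa
  if (abs(x) < .NEUTRAL_EPS) return(rep(1, length(y)))
  out <- numeric(length(y))
  z <- y == 0
  out[z] <- omega_from_x(x)
  yv <- y[!z]
  if (x < 0) {
    ## q(y) = e^x expm1(-x y) / (-expm1(x)); log form if expm1 overflows
    u <- -x * yv
    v <- ifelse(u < 700,
                exp(x) * expm1(u) / (-expm1(x)) / yv,
                exp(x + u - log(-expm1(x)) - log(yv)))
    out[!z] <- v
  } else {
    out[!z] <- expm1(-x * yv) / (expm1(-x) * yv)
  }
  out
}

#' Equilibrium intensity of the frequency spectrum (omega * psi)
#'
#' The product \eqn{\omega_{\gamma,\kappa}\,\psi_{\gamma,\kappa}(y)}, i.e.
#' the equilibrium intensity density per unit mutation intensity.  It
#' satisfies the identity
#' \eqn{\omega\psi(y) = 2\kappa\, q_{\gamma,\kappa}(1-y) / (y(1-y))},
#' which is finite and overflow-free for any strength of selection and is
#' used for all quadrature.
#'
#' @inheritParams sfs_density
#' @return Positive intensity values.
#' @export
sfs_intensity <- function(y, regime, kappa = 1) {
  regime <- as_regime(regime, if (missing(kappa)) NULL else kappa)
  if (any(!is.finite(y)) || any(y <= 0) || any(y >= 1)) {
    stop("'y' must lie in (0, 1)")
  }
  2 * regime$kappa * fixation_prob(1 - y, regime) / (y * (1 - y))
}

#' Equilibrium allele-frequency-spectrum functional
#'
#' Expected value of a site functional under the equilibrium Poisson random
#' field in a population of constant size `kappa * N`:
#' \deqn{\theta\,\omega_{\gamma,\kappa} f(1)\, t +
#'       \theta \int_0^1 f(y)\, \omega_{\gamma,\kappa}\psi_{\gamma,\kappa}(y)\, dy.}
#' The first term counts fixations accumulated linearly over \[0, t\]; the
#' second is the stationary polymorphic mass.  The integral is computed by
#' adaptive quadrature on the bounded integrand
#' \eqn{f(y)\, 2\kappa\, q(1-y)/(y(1-y))}; `f(y)` must vanish at least
#' linearly as `y -> 0` for the integral to exist.
#'
#' @param f vectorized function on \[0, 1\] (e.g. [f_pw] or [f_fix]).
#' @param regime a [selection_regime] (or numeric gamma with `kappa`).
#' @param theta population mutation intensity.
#' @param t elapsed time in units of N generations (enters the fixation
#'   term only).
#' @param kappa size ratio used when `regime` is numeric.
#' @param rel.tol requested relative quadrature accuracy.
#' @return An object of class `spectrum_functional`: a list with elements
#'   `fixation_mass`, `polymorphic_mass`, `total` and `rel_error`.
#' @examples
#' eq <- equilibrium_functional(f_pw, selection_regime(0, 1), theta = 1, t = 1)
#' eq$polymorphic_mass  # 2 * theta * kappa = 2
#' @export
equilibrium_functional <- function(f, regime, theta, t, kappa = 1,
                                   rel.tol = 1e-10) {
  regime <- as_regime(regime, if (missing(kappa)) NULL else kappa)
  stopifnot(theta > 0, t >= 0)
  f1 <- f(1)
  fixation_mass <- theta * fixation_rate(regime) * f1 * t
  if (is_fix_indicator(f)) {
    poly <- 0
    rel_error <- 0
  } else {
    q <- tryCatch(
      stats::integrate(function(y) f(y) * sfs_intensity(y, regime),
                       0, 1, rel.tol = rel.tol, subdivisions = 500L),
      error = function(e) stop("quadrature of the spectrum functional failed: ",
                               conditionMessage(e)))
    poly <- theta * q$value
    rel_error <- if (q$value != 0) q$abs.error / abs(q$value) else 0
    if (rel_error > 1e-8) {
      warning(sprintf("quadrature relative error %.2e exceeds 1e-8", rel_error))
    }
  }
  spectrum_functional(fixation_mass, poly, rel_error = rel_error)
}

spectrum_functional <- function(fixation_mass, polymorphic_mass,
                                se = 0, rel_error = NA_real_) {
  structure(list(fixation_mass = fixation_mass,
                 polymorphic_mass = polymorphic_mass,
                 total = fixation_mass + polymorphic_mass,
                 se = se, rel_error = rel_error),
            class = "spectrum_functional")
}

#' @export
print.spectrum_functional <- function(x, ...) {
  cat(sprintf(paste0("Spectrum functional: fixation mass %.6g + ",
                     "polymorphic mass %.6g = %.6g\n"),
              x$fixation_mass, x$polymorphic_mass, x$total))
  invisible(x)
}

#' Equilibrium nucleotide diversity of a selected class
#'
#' Closed-form expected pairwise diversity at equilibrium in a population of
#' size `kappa * N`:
#' \deqn{\pi_{\gamma,\kappa} = 4\theta\kappa\left(\frac{1}{1 - e^{-2\gamma\kappa}}
#'       - \frac{1}{2\gamma\kappa}\right)
#'       = 4\theta\kappa\,\frac{\omega_{\gamma,\kappa} - 1}{2\gamma\kappa},}
#' with neutral limit \eqn{2\theta\kappa} and limit 0 under strong purifying
#' selection.
#'
#' @inheritParams equilibrium_functional
#' @return Positive scalar diversity.
#' @examples
#' pi_equilibrium(selection_regime(-1, 1), theta = 1)  # ~1.37393
#' @export
pi_equilibrium <- function(regime, theta = 1, kappa = 1) {
  regime <- as_regime(regime, if (missing(kappa)) NULL else kappa)
  x <- 2 * regime$gamma * regime$kappa
  if (abs(x) < 1e-5) {
    ## series of 4*kappa*(omega - 1)/x around x = 0
    theta * 4 * regime$kappa * (0.5 + x / 12 - x^3 / 720)
  } else {
    theta * 4 * regime$kappa * (omega_from_x(x) - 1) / x
  }
}

#' Weighted equilibrium fixation-rate ratio
#'
#' Time-weighted mixture of the ancestral and new equilibrium fixation-rate
#' ratios, \eqn{\omega_w(t) = [t^* \omega_1 + (t - t^*)\omega_\kappa] / t}.
#' This is the classical stationary shortcut for a population-size change:
#' it ignores the transient dynamics of allele frequencies and serves as the
#' comparison point for the genuinely nonequilibrium ratio [omega_bar()].
#'
#' @param t evaluation time(s), `> 0`, with `t >= tstar`.
#' @param tstar time of the size change, `0 < tstar <= t`.
#' @param omega_anc equilibrium ratio of the ancestral population.
#' @param omega_new equilibrium ratio of the post-change population.
#' @return Weighted ratio, same length as `t`.
#' @export
omega_weighted <- function(t, tstar, omega_anc, omega_new) {
  if (any(t <= 0)) stop("'t' must be > 0")
  if (tstar <= 0) stop("'tstar' must be > 0")
  if (any(t < tstar)) stop("'t' must be >= 'tstar'")
  (tstar * omega_anc + (t - tstar) * omega_new) / t
}

#' Pairwise-difference and fixation-indicator functionals
#'
#' `f_pw(y) = 2 y (1 - y)` is the probability that a random pair of alleles
#' differs at a site with derived-allele frequency `y`; integrated against
#' the frequency spectrum it yields nucleotide diversity.  `f_fix` is the
#' indicator of frequency 1 and extracts the cumulative number of fixations
#' from the spectrum (it vanishes on the polymorphic interior).
#'
#' @param y frequency (vector) in \[0, 1\].
#' @return Function values, same length as `y`.
#' @export
f_pw <- function(y) 2 * y * (1 - y)

#' @rdname f_pw
#' @export
f_fix <- structure(function(y) as.numeric(y == 1),
                   fixation_indicator = TRUE)

is_fix_indicator <- function(f) isTRUE(attr(f, "fixation_indicator"))
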