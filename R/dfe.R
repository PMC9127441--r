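## Negative Gamma distribution of fitness effects (DFE) and numerical
## expectation of functions of the scaled selection coefficient over it.

#' Negative Gamma distribution of fitness effects
#'
#' The scaled selection coefficient of a new nonsynonymous mutation is
#' modeled as `V = -U` with `U ~ Gamma(shape, scale)`, i.e. density
#' \deqn{h_V(v) = \frac{(-v)^{a-1} e^{v/b}}{b^a \Gamma(a)}, \quad v \le 0,}
#' with mean `-shape * scale`.  All mass is deleterious; beneficial
#' mutations are outside the model.  `gamma_min` is the most negative
#' selection coefficient the stochastic engines simulate; expectations can
#' either integrate the full distribution or treat the tail beyond
#' `gamma_min` as contributing zero (see [dfe_expectation()]).
#'
#' @param shape Gamma shape parameter `a > 0`.
#' @param scale Gamma scale parameter `b > 0` (units of gamma).  Exactly one
#'   of `scale` and `mean` must be given.
#' @param mean mean of `V` (negative); sets `scale = -mean / shape`.
#' @param gamma_min truncation bound used by the simulation engines
#'   (negative; default -1000).
#' @return An object of class `gamma_dfe`.
#' @examples
#' gamma_dfe(shape = 0.15, mean = -2500)
#' @export
gamma_dfe <- function(shape, scale = NULL, mean = NULL, gamma_min = -1000) {
  stopifnot(shape > 0, gamma_min < 0)
  if (is.null(scale) == is.null(mean)) {
    stop("give exactly one of 'scale' and 'mean'")
  }
  if (is.null(scale)) {
    if (mean >= 0) stop("'mean' must be negative")
    scale <- -mean / shape
  }
  stopifnot(scale > 0)
  structure(list(shape = shape, scale = scale, gamma_min = gamma_min),
            class = "gamma_dfe")
}

#' @export
print.gamma_dfe <- function(x, ...) {
  cat(sprintf(paste0("Negative Gamma DFE: shape a = %g, scale b = %g ",
                     "(mean %g); simulated range bounded at %g ",
                     "(tail mass %.4g)\n"),
              x$shape, x$scale, -x$shape * x$scale, x$gamma_min,
              dfe_tail_mass(x)))
  invisible(x)
}

#' DFE density
#'
#' Density of the negative Gamma distribution of fitness effects at scaled
#' selection value `v <= 0`.  For `shape < 1` the density diverges as
#' `v -> 0-`; the singularity is integrable.
#'
#' @param v selection values, all `<= 0`.
#' @param dfe a [gamma_dfe].
#' @return Density values.
#' @export
dfe_density <- function(v, dfe) {
  if (any(v > 0)) stop("'v' must be <= 0")
  stats::dgamma(-v, shape = dfe$shape, scale = dfe$scale)
}

#' Gamma mass beyond the simulated selection range
#'
#' Probability that the DFE draws a selection coefficient more negative than
#' `gamma_min`.  With a small shape parameter this mass is not negligible,
#' although such mutations contribute essentially nothing to diversity or
#' fixations.
#'
#' @param dfe a [gamma_dfe].
#' @return Probability in \[0, 1\].
#' @export
dfe_tail_mass <- function(dfe) {
  stats::pgamma(-dfe$gamma_min, shape = dfe$shape, scale = dfe$scale,
                lower.tail = FALSE)
}

#' Quadrature rule for DFE expectations
#'
#' Gauss-Legendre nodes and weights for integrals against the negative
#' Gamma DFE.  The integrable endpoint singularity at `v = 0` (for
#' `shape < 1`) is removed exactly by the substitution `u = w^(1/a)` for
#' `u = -v`, under which the Gamma kernel `u^(a-1) du` becomes `dw / a`.
#'
#' @param dfe a [gamma_dfe].
#' @param n_nodes number of Gauss-Legendre nodes (default 200).
#' @param truncate if `TRUE`, nodes cover only `[gamma_min, 0]` and the
#'   weights sum to the covered mass (the tail is treated as contributing
#'   zero to the integrand); if `FALSE`, nodes cover the distribution up to
#'   the `1 - 1e-13` Gamma quantile and weights sum to 1.
#' @return List with `gamma` (negative node values), `weights`
#'   (incorporating the DFE density; no renormalization), `tail_mass`, and
#'   `truncate`.
#' @export
dfe_quadrature <- function(dfe, n_nodes = 200, truncate = TRUE) {
  a <- dfe$shape
  b <- dfe$scale
  u_max <- if (truncate) {
    -dfe$gamma_min
  } else {
    stats::qgamma(1e-13, shape = a, scale = b, lower.tail = FALSE)
  }
  gl <- pracma::gaussLegendre(n_nodes, 0, u_max^a)
  u <- gl$x^(1 / a)
  log_const <- -(a * log(b) + lgamma(a) + log(a))
  w <- gl$w * exp(-u / b + log_const)
  list(gamma = -u, weights = w,
       tail_mass = dfe_tail_mass(dfe), truncate = truncate)
}

#' Expectation of a function of the selection coefficient over the DFE
#'
#' Computes `E[g(V)]` for the negative Gamma DFE, either by transformed
#' Gauss-Legendre quadrature (deterministic) or by seeded Monte-Carlo
#' sampling (with a standard error).  In truncated mode, integration stops
#' at `gamma_min` and the tail is treated as contributing zero -- the
#' convention matched by the Wright-Fisher engine, which never simulates
#' selection stronger than `gamma_min`.  For integrands such as the
#' fixation rate or diversity, which vanish at strong selection, the two
#' modes agree closely; for unbounded integrands (e.g. `g(v) = v`) only the
#' untruncated mode recovers the full-distribution value.
#'
#' @param g vectorized function of the (negative) selection coefficient.
#' @param dfe a [gamma_dfe].
#' @param method `"quadrature"` (default) or `"mc"`.
#' @param n_nodes quadrature nodes.
#' @param truncate integrate only over `[gamma_min, 0]` (tail-zero
#'   convention).  Default `FALSE`: full distribution.
#' @param n_draws Monte-Carlo sample size.
#' @param seed Monte-Carlo seed.
#' @param check if `TRUE`, quadrature is repeated at ~70% of the nodes and a
#'   warning is issued if the two estimates differ by more than `1e-6`
#'   relative.
#' @return List with `value`, `se` (0 for quadrature), `method`,
#'   `tail_mass`.
#' @examples
#' dfe <- gamma_dfe(0.15, mean = -2500)
#' dfe_expectation(function(v) v, dfe)$value  # -2500
#' @export
dfe_expectation <- function(g, dfe, method = c("quadrature", "mc"),
                            n_nodes = 200, truncate = FALSE,
                            n_draws = 1e5, seed = NULL, check = TRUE) {
  method <- match.arg(method)
  if (method == "quadrature") {
    qd <- dfe_quadrature(dfe, n_nodes, truncate)
    value <- sum(qd$weights * g(qd$gamma))
    if (check) {
      qd2 <- dfe_quadrature(dfe, max(20L, ceiling(0.7 * n_nodes)), truncate)
      v2 <- sum(qd2$weights * g(qd2$gamma))
      if (abs(v2 - value) > 1e-6 * max(abs(value), 1e-12)) {
        warning(sprintf(
          "DFE quadrature may not have converged (rel. change %.2e); increase n_nodes",
          abs(v2 - value) / max(abs(value), 1e-12)))
      }
    }
    if (truncate && qd$tail_mass > 1e-3) {
      log_msg("WARN", sprintf(
        "DFE mass %.3g beyond gamma_min = %g is treated as contributing zero",
        qd$tail_mass, dfe$gamma_min), verbose = FALSE)
    }
    list(value = value, se = 0, method = method, tail_mass = qd$tail_mass)
  } else {
    if (!is.null(seed)) set.seed(seed)
    u <- stats::rgamma(n_draws, shape = dfe$shape, scale = dfe$scale)
    gv <- g(-u)
    if (truncate) gv[u > -dfe$gamma_min] <- 0
    list(value = mean(gv), se = stats::sd(gv) / sqrt(n_draws),
         method = method, tail_mass = dfe_tail_mass(dfe))
  }
}
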