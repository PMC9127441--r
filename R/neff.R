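## Effective-population-size proxies: the diversity-based (microevolutionary,
## snapshot) size and the harmonic-mean (macroevolutionary, variance-type)
## size over the window [0, t].

#' Diversity-based effective population size
#'
#' Scaled synonymous diversity, \eqn{N_{eff}^{\pi}(t) = \pi_S(t) / (2 L \mu)}
#' with per-site mutation rate \eqn{\mu = \theta / (L N)}; the number of
#' sites cancels, leaving \eqn{N \pi_S(t) / (2\theta)}.  Equals the census
#' size `N` at the ancestral equilibrium and `kappa * N` long after the
#' change; it tracks a size change on the fast (microevolutionary)
#' timescale of segregating variation.
#'
#' @param pi_s_value synonymous diversity value(s), `> 0`.
#' @param params a [model_params] (uses `theta` and `N`).
#' @return Effective sizes, same length as `pi_s_value`.
#' @export
neff_pi <- function(pi_s_value, params) {
  if (any(pi_s_value <= 0)) stop("'pi_s_value' must be positive")
  params$N * pi_s_value / (2 * params$theta)
}

#' Harmonic-mean effective population size
#'
#' Reciprocal of the time-averaged genetic drift over \[0, t\]:
#' \deqn{N_{eff}^{h}(t) = \Big(\frac1t \int_0^t \frac{ds}{N_\kappa(s)}\Big)^{-1},}
#' which for a single change at `t*` equals
#' \eqn{\kappa N t / (t^*(\kappa - 1) + t)}, with value `N` at `t = t*` and
#' limit `kappa * N`.  For `t` before the first change it equals the
#' ancestral size.  Implemented for arbitrary step histories via the same
#' harmonic integral.
#'
#' @param t evaluation times, all `> 0`.
#' @param history a [size_history].
#' @return Effective sizes, same length as `t`.
#' @examples
#' h <- size_history(1000, 1, c(1, 4))
#' neff_h(20, h)  # 80000 / 23
#' @export
neff_h <- function(t, history) {
  if (any(t <= 0)) stop("'t' must be > 0")
  bounds <- c(0, history$change_times, Inf)
  vapply(t, function(tt) {
    upper <- pmin(bounds[-1], tt)
    lower <- pmin(bounds[-length(bounds)], tt)
    integral <- sum(pmax(upper - lower, 0) / history$kappas)
    history$N_ref * tt / integral
  }, 0)
}
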