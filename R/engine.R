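## Engine indirection: the nonequilibrium functionals consume path
## expectations E_y[f(xi_t)] and fixation-time distributions P_y(tau_1 <= t)
## through a small interface, so that the deterministic PDE solver and the
## Wright-Fisher Monte-Carlo tables are interchangeable.

#' Expectation engines
#'
#' Construct the engine that supplies path expectations to the
#' nonequilibrium spectrum functionals.  `engine_pde()` solves the backward
#' Kolmogorov equation (deterministic, the default); `engine_wf()` builds
#' Monte-Carlo tables from discrete Wright-Fisher simulation on a
#' log-spaced frequency grid and interpolates them.
#'
#' Both return a list with fields
#' `type`, `y` (frequency grid on which expectations are tabulated),
#' `moments(f, gamma_eff, ref_times)` returning `list(values, se)` with one
#' column per time, and (PDE only) `propagate(v, gamma_eff, duration)` used
#' for multi-epoch histories.  Times are in reference-population units; the
#' caller applies the `kappa` time/selection rescaling.
#'
#' @param n_y number of PDE grid intervals.
#' @param dt target PDE time step.
#' @param cfg a [wf_config] controlling the Wright-Fisher tables.
#' @param y_grid frequency grid for the Wright-Fisher tables; default
#'   `1/N` plus `n_points` log-spaced values up to `1 - 1/N`.
#' @param n_points number of log-spaced grid points.
#' @return An engine object of class `afs_engine`.
#' @export
engine_pde <- function(n_y = 2000, dt = 0.01) {
  y <- (0:n_y) / n_y
  eng <- list(
    type = "pde",
    y = y,
    moments = function(f, gamma_eff, ref_times) {
      ord <- order(ref_times)
      sol <- kbe_solve(f, gamma_eff, ref_times[ord], n_y = n_y, dt = dt)
      vals <- sol$values
      vals[, ord] <- vals
      list(values = vals, se = NULL)
    },
    propagate = function(v, gamma_eff, duration) {
      if (duration <= 0) return(v)
      kbe_solve(v, gamma_eff, duration, n_y = n_y, dt = dt)$values[, 1]
    })
  structure(eng, class = "afs_engine")
}

#' @rdname engine_pde
#' @export
engine_wf <- function(cfg = wf_config(), y_grid = NULL, n_points = 40) {
  if (is.null(y_grid)) {
    N <- cfg$N
    y_grid <- unique(sort(c(1 / N, exp(seq(log(1 / N), log(1 - 1 / N),
                                           length.out = n_points)))))
  }
  eng <- list(
    type = "wf",
    y = y_grid,
    cfg = cfg,
    moments = function(f, gamma_eff, ref_times) {
      regime <- selection_regime(gamma_eff, 1)
      nv <- matrix(NA_real_, length(y_grid), length(ref_times))
      se <- matrix(NA_real_, length(y_grid), length(ref_times))
      for (i in seq_along(y_grid)) {
        if (is_fix_indicator(f)) {
          est <- estimate_fixation_cdf(y_grid[i], regime, ref_times, cfg)
          nv[i, ] <- est$cdf
          se[i, ] <- est$se
        } else {
          est <- estimate_moment(f, y_grid[i], regime, ref_times, cfg)
          nv[i, ] <- est$values
          se[i, ] <- est$se
        }
      }
      list(values = nv, se = se)
    },
    propagate = NULL)
  structure(eng, class = "afs_engine")
}

#' @export
print.afs_engine <- function(x, ...) {
  cat(sprintf("AFS expectation engine: %s (%d frequency grid points)\n",
              x$type, length(x$y)))
  invisible(x)
}

resolve_engine <- function(engine) {
  if (inherits(engine, "afs_engine")) return(engine)
  if (is.character(engine)) {
    return(switch(match.arg(engine, c("pde", "wf")),
                  pde = engine_pde(), wf = engine_wf()))
  }
  stop("'engine' must be an afs_engine or \"pde\"/\"wf\"")
}
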