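## Orchestration: kappa sweeps across the standard figure grids, the
## selection-drift table relating measures of selection to effective-size
## proxies, and log-log slope fitting.

#' Analysis run configuration
#'
#' Collects every parameter of a kappa-sweep analysis with the standard
#' defaults: theta = 1, N = 1000, Gamma DFE with shape 0.15 and mean -2500,
#' kappa grid \{0.1, 0.25, 0.5, 1, 2, 4\}, an ancient change at t* = 1 and
#' evaluation times \{2, 10, 20\}.
#'
#' @param theta population mutation intensity.
#' @param N reference haploid population size.
#' @param dfe a [gamma_dfe].
#' @param kappas positive size ratios to sweep.
#' @param tstar time of the size change.
#' @param times evaluation times (all `> tstar` is typical).
#' @param engine `"pde"` or `"wf"`, or an [engine_pde()] / [engine_wf()]
#'   object.
#' @param n_nodes DFE quadrature nodes.
#' @param truncate tail-zero truncation of the DFE at `gamma_min`.
#' @param seed master seed (used by the Wright-Fisher engine).
#' @param out_dir output directory for the command-line interface.
#' @return A list of class `run_config`.
#' @export
run_config <- function(theta = 1, N = 1000,
                       dfe = gamma_dfe(0.15, mean = -2500),
                       kappas = c(0.1, 0.25, 0.5, 1, 2, 4),
                       tstar = 1, times = c(2, 10, 20),
                       engine = "pde", n_nodes = 32, truncate = TRUE,
                       seed = 1, out_dir = ".") {
  stopifnot(length(kappas) >= 1, all(kappas > 0), theta > 0, N >= 2,
            tstar > 0, all(times > 0))
  structure(list(theta = theta, N = N, dfe = dfe, kappas = kappas,
                 tstar = tstar, times = times, engine = engine,
                 n_nodes = n_nodes, truncate = truncate,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Equilibrium kappa sweep
#'
#' DFE-averaged equilibrium values of the two measures of selection for a
#' range of population sizes `kappa * N`: the diversity ratio
#' `E[pi_N(V, kappa)] / (2 theta kappa)` and the fixation-rate ratio
#' `E[omega(V, kappa)]`.  At selection-drift balance both decline
#' approximately as a power of the effective size with exponent given by
#' the DFE shape parameter.
#'
#' @param cfg a [run_config].
#' @return Data frame with one row per kappa: `kappa`, `neff`, `pin_pis`,
#'   `omega`, and their logs.
#' @export
equilibrium_sweep <- function(cfg = run_config()) {
  qd <- dfe_quadrature(cfg$dfe, cfg$n_nodes, cfg$truncate)
  rows <- lapply(cfg$kappas, function(kap) {
    pin <- sum(qd$weights * vapply(qd$gamma, function(g) {
      pi_equilibrium(selection_regime(g, kap), cfg$theta)
    }, 0))
    om <- sum(qd$weights * vapply(qd$gamma, function(g) {
      fixation_rate(selection_regime(g, kap))
    }, 0))
    data.frame(kappa = kap, neff = kap * cfg$N,
               pin_pis = pin / (2 * cfg$theta * kap), omega = om)
  })
  out <- do.call(rbind, rows)
  out$log_neff <- log(out$neff)
  out$log_pin_pis <- log(out$pin_pis)
  out$log_omega <- log(out$omega)
  out
}

#' Selection-drift table after a change in population size
#'
#' For every combination of `kappa` and evaluation time, computes the
#' nonequilibrium measures of selection (`pin_pis`, `omega_bar`) and the
#' two effective-size proxies (`neff_pi`, `neff_h`), with their logarithms
#' -- the coordinates of the log-log selection-drift relationship.  Rows
#' that fail (e.g. an engine error for one kappa) are logged and dropped
#' rather than aborting the sweep.
#'
#' @param cfg a [run_config].
#' @return Data frame of class `drift_selection_table`, one row per
#'   `(kappa, time)`.
#' @export
drift_selection_table <- function(cfg = run_config()) {
  engine <- resolve_engine(cfg$engine)
  params <- model_params(theta = cfg$theta, N = cfg$N, tstar = cfg$tstar,
                         t_present = max(cfg$times))
  rows <- list()
  for (kap in cfg$kappas) {
    row <- tryCatch({
      hist_k <- size_history(cfg$N, cfg$tstar, c(1, kap))
      ms <- measure_series(cfg$dfe, hist_k, cfg$theta, cfg$times,
                           engine, cfg$n_nodes, cfg$truncate)
      data.frame(kappa = kap, time = ms$time,
                 pin_pis = ms$pin_pis, omega_bar = ms$omega_bar,
                 neff_pi = ms$neff_pi, neff_h = ms$neff_h)
    }, error = function(e) {
      log_msg("ERROR", sprintf("kappa = %g failed: %s", kap,
                               conditionMessage(e)), verbose = TRUE)
      NULL
    })
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  out$log_pin_pis <- log(out$pin_pis)
  out$log_omega_bar <- log(out$omega_bar)
  out$log_neff_pi <- log(out$neff_pi)
  out$log_neff_h <- log(out$neff_h)
  class(out) <- c("drift_selection_table", class(out))
  out
}

#' Least-squares slope on the log-log scale
#'
#' Ordinary least squares of `log(y)` on `log(x)`.  At selection-drift
#' balance with a Gamma DFE the fitted slope approximates the negative of
#' the DFE shape parameter.
#'
#' @param x positive predictor values (at least two distinct).
#' @param y positive response values.
#' @return Named vector `c(slope, intercept)`.
#' @examples
#' fit_loglog_slope(c(100, 1000, 4000), c(100, 1000, 4000)^-0.15)
#' @export
fit_loglog_slope <- function(x, y) {
  if (length(x) < 2 || length(x) != length(y)) {
    stop("need at least two (x, y) pairs of equal length")
  }
  if (any(x <= 0) || any(y <= 0)) stop("'x' and 'y' must be positive")
  lx <- log(x)
  if (diff(range(lx)) < 1e-12) stop("degenerate spread in 'x'")
  fit <- stats::lm.fit(cbind(intercept = 1, slope = lx), log(y))
  c(slope = unname(fit$coefficients["slope"]),
    intercept = unname(fit$coefficients["intercept"]))
}
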