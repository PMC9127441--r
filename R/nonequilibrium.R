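## The nonstationary allele frequency spectrum after one or several step
## changes in population size, and the time-dependent measures built from
## it: piN(t), piS(t), piN/piS, cumulative fixations Z(t), and the
## fixation-rate ratio omega_bar(t).

#' Step-function population size history
#'
#' The population size over time is `N_ref * kappa(t)`, a step function:
#' `kappa(t) = kappas[1]` before the first change time and `kappas[k + 1]`
#' from `change_times[k]` on.  A single-change history (the primary case)
#' has one change time `tstar` and `kappas = c(1, kappa)`.
#'
#' @param N_ref reference haploid population size.
#' @param change_times strictly increasing, positive change times (units of
#'   `N_ref` generations); may be empty for a constant population.
#' @param kappas size ratios, one more than `length(change_times)`; the
#'   first is the ancestral ratio (1 in the standard setup).
#' @return An object of class `size_history`.
#' @examples
#' size_history(1000, 1, c(1, 4))     # N -> 4N at t* = 1
#' @export
size_history <- function(N_ref = 1000, change_times = numeric(),
                         kappas = 1) {
  stopifnot(N_ref >= 2, length(kappas) == length(change_times) + 1L,
            all(kappas > 0), all(change_times > 0))
  if (is.unsorted(change_times, strictly = TRUE)) {
    stop("'change_times' must be strictly increasing")
  }
  structure(list(N_ref = N_ref, change_times = as.numeric(change_times),
                 kappas = as.numeric(kappas)),
            class = "size_history")
}

#' @export
print.size_history <- function(x, ...) {
  if (length(x$change_times) == 0) {
    cat(sprintf("Constant population: N = %g * %g\n", x$N_ref, x$kappas[1]))
  } else {
    cat(sprintf("Size history (N_ref = %g): kappa %s with changes at t = %s\n",
                x$N_ref, paste(x$kappas, collapse = " -> "),
                paste(x$change_times, collapse = ", ")))
  }
  invisible(x)
}

#' @rdname size_history
#' @param t time(s).
#' @export
kappa_at <- function(history, t) {
  idx <- findInterval(t, history$change_times) + 1L
  history$kappas[idx]
}

n_changes <- function(history) length(history$change_times)

single_change <- function(history) {
  if (n_changes(history) != 1L) {
    stop("this operation requires a single-change size history; ",
         "use afs_functional_multi() for multi-epoch histories")
  }
  list(tstar = history$change_times[1],
       kappa0 = history$kappas[1], kappa = history$kappas[2])
}

## integral of u(y) * [nu_{gamma,kappa_old} - nu_{gamma,kappa_new}](y) dy
## with the 1/y endpoint behavior handled analytically.  `u` is a matrix of
## engine expectations (rows = engine$y, columns = times).
transient_integral <- function(u, se, engine, gamma, kappa_old, kappa_new) {
  r_old <- selection_regime(gamma, kappa_old)
  r_new <- selection_regime(gamma, kappa_new)
  nt <- ncol(u)
  out <- numeric(nt)
  out_se <- numeric(nt)
  if (engine$type == "pde") {
    y <- engine$y
    n <- length(y)
    yi <- y[2:(n - 1)]
    br <- sfs_intensity(yi, r_old) - sfs_intensity(yi, r_new)
    br0_y <- 2 * (kappa_old - kappa_new)                 # limit of y * bracket
    br1 <- 2 * kappa_old * fixation_rate(r_old) -
      2 * kappa_new * fixation_rate(r_new)               # limit at y = 1
    for (j in seq_len(nt)) {
      g <- c((u[2, j] / y[2]) * br0_y, u[2:(n - 1), j] * br, u[n, j] * br1)
      out[j] <- trapz_grid(y, g)
    }
  } else {
    y <- engine$y
    for (j in seq_len(nt)) {
      h_app <- stats::approxfun(log(y), u[, j] / y, rule = 2)
      ybr <- function(z) {
        2 * kappa_old * q_over_y(1 - z, r_old) -
          2 * kappa_new * q_over_y(1 - z, r_new)
      }
      out[j] <- stats::integrate(function(z) h_app(log(z)) * ybr(z),
                                 0, 1, rel.tol = 1e-8,
                                 subdivisions = 500L)$value
      if (!is.null(se)) {
        w <- trapz_weights(y)
        br_nodes <- sfs_intensity(y, r_old) - sfs_intensity(y, r_new)
        out_se[j] <- sqrt(sum((w * br_nodes * se[, j])^2))
      }
    }
  }
  list(value = out, se = out_se)
}

#' Nonequilibrium allele-frequency-spectrum functional (single change)
#'
#' Expected value of a site functional over the Poisson random field at
#' time `t` in a population that changed size once at `t*`.  For
#' `t <= t*` this is the ancestral equilibrium spectrum; for `t > t*` it
#' consists of the accumulated fixation term, the new-equilibrium
#' polymorphic mass, and a transient term that weighs the path expectation
#' \eqn{E_y^{\gamma,\kappa}[f(\xi_{t - t^*})]} by the difference between the
#' ancestral and new equilibrium intensities:
#' \deqn{\theta f(1)[\omega_{\gamma,1} t^* + \omega_{\gamma,\kappa}(t-t^*)]
#'  + \theta\int_0^1 f\,\omega_{\gamma,\kappa}\psi_{\gamma,\kappa}\,dy
#'  + \theta\int_0^1 E_y^{\gamma,\kappa}[f(\xi_{t-t^*})]
#'    [\omega_{\gamma,1}\psi_{\gamma,1} - \omega_{\gamma,\kappa}\psi_{\gamma,\kappa}]\,dy.}
#'
#' @param f vectorized function on \[0, 1\] (use [f_fix] for fixations).
#' @param regime a [selection_regime] or numeric gamma; its `kappa` is
#'   ignored -- the size ratio comes from `history`.
#' @param history a single-change [size_history].
#' @param theta population mutation intensity.
#' @param t evaluation time (scalar, `>= 0`).
#' @param engine an [engine_pde()] or [engine_wf()] object, or `"pde"` /
#'   `"wf"`.
#' @return A `spectrum_functional` (see [equilibrium_functional()]); `se`
#'   carries the Monte-Carlo uncertainty of the transient term when the
#'   Wright-Fisher engine is used.
#' @export
afs_functional <- function(f, regime, history, theta, t,
                           engine = engine_pde()) {
  regime <- as_regime(regime)
  engine <- resolve_engine(engine)
  stopifnot(t >= 0, theta > 0)
  if (n_changes(history) == 0L) {
    return(equilibrium_functional(f, selection_regime(regime$gamma,
                                                      history$kappas[1]),
                                  theta, t))
  }
  sc <- single_change(history)
  if (t <= sc$tstar) {
    return(equilibrium_functional(f, selection_regime(regime$gamma, sc$kappa0),
                                  theta, t))
  }
  gamma <- regime$gamma
  r_old <- selection_regime(gamma, sc$kappa0)
  r_new <- selection_regime(gamma, sc$kappa)
  f1 <- f(1)
  fix <- theta * f1 * (fixation_rate(r_old) * sc$tstar +
                         fixation_rate(r_new) * (t - sc$tstar))
  poly_eq <- if (is_fix_indicator(f)) 0 else {
    equilibrium_functional(f, r_new, theta, 0)$polymorphic_mass
  }
  mom <- engine$moments(f, gamma * sc$kappa, (t - sc$tstar) / sc$kappa)
  tr <- transient_integral(mom$values, mom$se, engine, gamma,
                           sc$kappa0, sc$kappa)
  spectrum_functional(fix, poly_eq + theta * tr$value,
                      se = theta * tr$se)
}

#' Nonequilibrium spectrum functional for multi-epoch histories
#'
#' Generalizes [afs_functional()] to a step history with several size
#' changes.  Each change leaves a deficit between the equilibrium
#' intensities of the adjoining epochs; the deficit created at change `k`
#' relaxes under the (piecewise) diffusion dynamics from `t*_k` to `t`, so
#' its path expectation is computed by chaining the PDE propagator through
#' the intervening epochs (effective selection `gamma * kappa_j`, duration
#' rescaled by `kappa_j` in each).  With a single change the result reduces
#' exactly to [afs_functional()].  Requires the PDE engine.
#'
#' @inheritParams afs_functional
#' @param history a [size_history] (any number of changes).
#' @return A `spectrum_functional`.
#' @export
afs_functional_multi <- function(f, regime, history, theta, t,
                                 engine = engine_pde()) {
  regime <- as_regime(regime)
  engine <- resolve_engine(engine)
  if (is.null(engine$propagate)) {
    stop("multi-epoch functionals require the PDE engine")
  }
  stopifnot(t >= 0, theta > 0)
  gamma <- regime$gamma
  ct <- history$change_times
  m <- sum(ct < t)          # changes that have occurred strictly before t
  bounds <- c(0, ct[seq_len(m)], t)       # epoch boundaries within [0, t]
  kap <- history$kappas[seq_len(m + 1L)]  # ratio within each epoch
  durations <- diff(bounds)
  f1 <- f(1)
  omegas <- vapply(kap, function(k) {
    fixation_rate(selection_regime(gamma, k))
  }, 0)
  fix <- theta * f1 * sum(omegas * durations)
  r_last <- selection_regime(gamma, kap[m + 1L])
  poly_eq <- if (is_fix_indicator(f)) 0 else {
    equilibrium_functional(f, r_last, theta, 0)$polymorphic_mass
  }
  trans <- 0
  if (m > 0L) {
    v_base <- f(engine$y)   # deficit k propagates through epochs k..m
    v <- v_base
    for (k in m:1) {
      ## after this loop step, v = E_y[ f(path from t*_k to t) ]
      epoch_kappa <- kap[k + 1L]
      v <- engine$propagate(v, gamma * epoch_kappa,
                            durations[k + 1L] / epoch_kappa)
      tr <- transient_integral(matrix(v, ncol = 1), NULL, engine, gamma,
                               kap[k], kap[k + 1L])
      trans <- trans + theta * tr$value
    }
  }
  spectrum_functional(fix, poly_eq + trans)
}

#' Synonymous nucleotide diversity after size changes (closed form)
#'
#' Neutral pairwise diversity \eqn{\pi_S(t)} under a step size history,
#' obtained from the exact relaxation of the neutral pairwise moment: the
#' diversity decays toward each epoch's equilibrium `2 * theta * kappa`
#' with time constant `kappa`,
#' \deqn{\pi_S(t) = 2\theta\kappa + (\pi_S(t^*) - 2\theta\kappa)
#'   e^{-(t - t^*)/\kappa}} within each epoch.  For the standard
#' single-change history this is
#' `2*theta` for `t <= t*` and
#' `2*theta*kappa + 2*theta*(1 - kappa) * exp(-(t - t*)/kappa)` after.
#'
#' @param history a [size_history].
#' @param theta population mutation intensity.
#' @param t evaluation times (vector, `>= 0`).
#' @return Diversity values, same length as `t`.
#' @export
pi_s_t <- function(history, theta, t) {
  stopifnot(all(t >= 0))
  out <- numeric(length(t))
  ct <- c(history$change_times, Inf)
  m_start <- 2 * theta * history$kappas[1]  # ancestral equilibrium
  t_start <- 0
  for (j in seq_along(history$kappas)) {
    kap <- history$kappas[j]
    eq <- 2 * theta * kap
    in_epoch <- t >= t_start & t < ct[j]
    out[in_epoch] <- eq + (m_start - eq) * exp(-(t[in_epoch] - t_start) / kap)
    m_start <- eq + (m_start - eq) * exp(-(ct[j] - t_start) / kap)
    t_start <- ct[j]
    if (!is.finite(t_start)) break
  }
  out
}

## per-gamma series of pi(t) and Z(t) under a single-change history,
## sharing one engine call per functional across all times past t*.
series_for_gamma <- function(gamma, history, theta, times, engine,
                             want_pi = TRUE, want_z = TRUE) {
  sc <- single_change(history)
  r_old <- selection_regime(gamma, sc$kappa0)
  r_new <- selection_regime(gamma, sc$kappa)
  past <- times > sc$tstar
  ref_times <- (times[past] - sc$tstar) / sc$kappa
  res <- list()
  if (want_pi) {
    pi_vec <- rep(pi_equilibrium(r_old, theta), length(times))
    pi_se <- numeric(length(times))
    if (any(past)) {
      mom <- engine$moments(f_pw, gamma * sc$kappa, ref_times)
      tr <- transient_integral(mom$values, mom$se, engine, gamma,
                               sc$kappa0, sc$kappa)
      pi_vec[past] <- pi_equilibrium(r_new, theta) + theta * tr$value
      pi_se[past] <- theta * tr$se
    }
    res$pi <- pi_vec
    res$pi_se <- pi_se
  }
  if (want_z) {
    z_vec <- theta * fixation_rate(r_old) * pmin(times, sc$tstar)
    z_se <- numeric(length(times))
    if (any(past)) {
      cdf <- engine$moments(f_fix, gamma * sc$kappa, ref_times)
      tr <- transient_integral(cdf$values, cdf$se, engine, gamma,
                               sc$kappa0, sc$kappa)
      z_vec[past] <- z_vec[past] +
        theta * fixation_rate(r_new) * (times[past] - sc$tstar) +
        theta * tr$value
      z_se[past] <- theta * tr$se
    }
    res$z <- z_vec
    res$z_se <- z_se
  }
  res
}

#' Nonsynonymous nucleotide diversity after a size change
#'
#' Time-dependent nonsynonymous diversity \eqn{\pi_N(t)}: the equilibrium
#' diversity of each selected class plus its transient relaxation after the
#' size change, averaged over the Gamma DFE by quadrature (the frequency
#' integral is innermost and one engine table is shared per DFE node).
#' Equal to the ancestral equilibrium for `t <= t*`, approaching the new
#' equilibrium as `t` grows.
#'
#' @param dfe a [gamma_dfe].
#' @param history a single-change [size_history].
#' @param theta population mutation intensity.
#' @param t evaluation times (vector).
#' @param engine expectation engine (see [engine_pde()]).
#' @param n_nodes DFE quadrature nodes.
#' @param truncate treat DFE mass beyond `gamma_min` as contributing zero
#'   (the convention of the simulation engines); default `TRUE`.
#' @return Diversity values with attribute `"se"`.
#' @export
pi_n_t <- function(dfe, history, theta, t, engine = engine_pde(),
                   n_nodes = 32, truncate = TRUE) {
  engine <- resolve_engine(engine)
  qd <- dfe_quadrature(dfe, n_nodes, truncate)
  acc <- numeric(length(t))
  var_acc <- numeric(length(t))
  for (i in seq_along(qd$gamma)) {
    s <- series_for_gamma(qd$gamma[i], history, theta, t, engine,
                          want_pi = TRUE, want_z = FALSE)
    acc <- acc + qd$weights[i] * s$pi
    var_acc <- var_acc + (qd$weights[i] * s$pi_se)^2
  }
  structure(acc, se = sqrt(var_acc))
}

#' Ratio of nonsynonymous and synonymous diversity
#'
#' Pointwise ratio `pi_n / pi_s` with first-order propagation of the engine
#' standard error of the numerator.
#'
#' @param pi_n numerator series (may carry an `"se"` attribute).
#' @param pi_s positive denominator series.
#' @return Ratio with attribute `"se"`.
#' @export
pin_pis_ratio <- function(pi_n, pi_s) {
  if (any(pi_s <= 0)) stop("'pi_s' must be positive")
  se <- attr(pi_n, "se")
  structure(as.numeric(pi_n) / pi_s,
            se = if (is.null(se)) NULL else se / pi_s)
}

#' Cumulative number of fixations after a size change
#'
#' Expected cumulative fixations Z(t) of a mutation class over \[0, t\]:
#' linear at rate `theta * omega` before the change; afterwards the two
#' equilibrium-rate terms plus a transient that weighs the fixation-time
#' distribution \eqn{P_y(\tau_1 \le t - t^*)} by the intensity deficit
#' between the epochs.
#'
#' @param regime a [selection_regime] or numeric gamma (its `kappa` is
#'   ignored; the size ratio comes from `history`).
#' @inheritParams pi_n_t
#' @return Cumulative fixation counts, same length as `t`, with attribute
#'   `"se"`.
#' @export
fixations_t <- function(regime, history, theta, t, engine = engine_pde()) {
  regime <- as_regime(regime)
  engine <- resolve_engine(engine)
  if (n_changes(history) == 0L) {
    r <- selection_regime(regime$gamma, history$kappas[1])
    return(structure(theta * fixation_rate(r) * t, se = numeric(length(t))))
  }
  s <- series_for_gamma(regime$gamma, history, theta, t, engine,
                        want_pi = FALSE, want_z = TRUE)
  structure(s$z, se = s$z_se)
}

#' Cumulative fixation-rate ratio omega_bar(t)
#'
#' Ratio of expected nonsynonymous (DFE-averaged) and synonymous (neutral)
#' cumulative fixations over \[0, t\] -- the population-level analogue of
#' dN/dS.  Equals the ancestral equilibrium ratio `E[omega_{V,1}]` for
#' `t <= t*` and approaches the new equilibrium `E[omega_{V,kappa}]` as `t`
#' grows, but lags behind the weighted-equilibrium shortcut
#' [omega_weighted()] because fixations accumulated under the ancestral
#' regime remain in the count.
#'
#' @inheritParams pi_n_t
#' @param t evaluation times, all `> 0`.
#' @return Ratio values with attribute `"se"`.
#' @export
omega_bar <- function(dfe, history, theta, t, engine = engine_pde(),
                      n_nodes = 32, truncate = TRUE) {
  if (any(t <= 0)) stop("omega_bar is undefined at t <= 0")
  engine <- resolve_engine(engine)
  qd <- dfe_quadrature(dfe, n_nodes, truncate)
  z_n <- numeric(length(t))
  var_acc <- numeric(length(t))
  for (i in seq_along(qd$gamma)) {
    s <- series_for_gamma(qd$gamma[i], history, theta, t, engine,
                          want_pi = FALSE, want_z = TRUE)
    z_n <- z_n + qd$weights[i] * s$z
    var_acc <- var_acc + (qd$weights[i] * s$z_se)^2
  }
  z_s <- fixations_t(0, history, theta, t, engine)
  structure(z_n / as.numeric(z_s), se = sqrt(var_acc) / as.numeric(z_s))
}

#' Time series of all selection and drift measures
#'
#' Evaluates, on one time grid, the synonymous and nonsynonymous diversity,
#' their ratio, cumulative synonymous and nonsynonymous fixations, the
#' fixation-rate ratio `omega_bar`, the weighted-equilibrium ratio
#' `omega_w`, and the two effective-size proxies.  One engine table per DFE
#' node and functional is shared across all times.
#'
#' @inheritParams pi_n_t
#' @param times evaluation times (all `> 0`).
#' @return A data frame with columns `time`, `pi_n`, `pi_s`, `pin_pis`,
#'   `z_n`, `z_s`, `omega_bar`, `omega_w`, `neff_pi`, `neff_h`, `engine`,
#'   `se_pi_n`, `se_z_n`, and attribute `"provenance"`.
#' @export
measure_series <- function(dfe, history, theta = 1,
                           times = seq(0.1, 20, by = 0.1),
                           engine = engine_pde(), n_nodes = 32,
                           truncate = TRUE) {
  stopifnot(all(times > 0))
  engine <- resolve_engine(engine)
  sc <- single_change(history)
  qd <- dfe_quadrature(dfe, n_nodes, truncate)
  pi_n <- z_n <- numeric(length(times))
  var_pi <- var_z <- numeric(length(times))
  omega_anc <- omega_new <- 0
  for (i in seq_along(qd$gamma)) {
    s <- series_for_gamma(qd$gamma[i], history, theta, times, engine)
    pi_n <- pi_n + qd$weights[i] * s$pi
    z_n <- z_n + qd$weights[i] * s$z
    var_pi <- var_pi + (qd$weights[i] * s$pi_se)^2
    var_z <- var_z + (qd$weights[i] * s$z_se)^2
    omega_anc <- omega_anc +
      qd$weights[i] * fixation_rate(selection_regime(qd$gamma[i], sc$kappa0))
    omega_new <- omega_new +
      qd$weights[i] * fixation_rate(selection_regime(qd$gamma[i], sc$kappa))
  }
  pi_s <- pi_s_t(history, theta, times)
  z_s <- as.numeric(fixations_t(0, history, theta, times, engine))
  omega_w <- ifelse(times <= sc$tstar, omega_anc,
                    (sc$tstar * omega_anc +
                       (times - sc$tstar) * omega_new) / times)
  df <- data.frame(time = times,
                   pi_n = pi_n, pi_s = pi_s, pin_pis = pi_n / pi_s,
                   z_n = z_n, z_s = z_s, omega_bar = z_n / z_s,
                   omega_w = omega_w,
                   neff_pi = history$N_ref * pi_s / (2 * theta),
                   neff_h = neff_h(times, history),
                   engine = engine$type,
                   se_pi_n = sqrt(var_pi), se_z_n = sqrt(var_z))
  attr(df, "provenance") <- list(
    theta = theta, N_ref = history$N_ref, tstar = sc$tstar,
    kappa = sc$kappa, dfe_shape = dfe$shape, dfe_scale = dfe$scale,
    gamma_min = dfe$gamma_min, n_nodes = n_nodes, truncate = truncate,
    engine = engine$type,
    omega_eq_ancestral = omega_anc, omega_eq_new = omega_new)
  df
}
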