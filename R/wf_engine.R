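## Discrete Wright-Fisher engine: binomial resampling with genic selection,
## vectorized across replicate paths.  Supplies Monte-Carlo estimates of the
## fixation-time distribution P_y(tau_1 <= t) and of conditional moments
## E_y[f(xi_t)], and a finite-(N, L) Poisson-field simulator of the whole
## collection of sites.

#' Wright-Fisher simulation configuration
#'
#' @param N simulated haploid population size.
#' @param n_gen generation horizon; paths not absorbed by then are censored
#'   and treated as never fixing.
#' @param reps_fix replicates for fixation-time distributions.  `NULL`
#'   selects 1e5 for neutral and 1e4 for selected classes at run time.
#' @param reps_moment replicates for moment estimates.
#' @param seed master seed; per-table seeds are derived from it and the
#'   table labels, so tables are reproducible independent of evaluation
#'   order.
#' @return An object of class `wf_config`.
#' @export
wf_config <- function(N = 1000, n_gen = 20000, reps_fix = NULL,
                      reps_moment = 1000, seed = 1) {
  stopifnot(N >= 2, n_gen >= 1, reps_moment >= 1)
  if (!is.null(reps_fix)) stopifnot(reps_fix >= 1)
  structure(list(N = as.integer(N), n_gen = as.integer(n_gen),
                 reps_fix = reps_fix, reps_moment = as.integer(reps_moment),
                 seed = as.integer(seed)),
            class = "wf_config")
}

reps_fix_for <- function(cfg, gamma_eff) {
  if (!is.null(cfg$reps_fix)) return(as.integer(cfg$reps_fix))
  if (abs(gamma_eff) < .NEUTRAL_EPS) 100000L else 10000L
}

## Core: evolve `reps` replicate counts forward, recording (optionally) the
## frequency of every replicate at the requested generations.  Absorbed
## paths stay at 0 or N.  Returns fixation generations (NA if lost or
## censored), a censoring flag, and the recorded frequency matrix.
wf_sim_batch <- function(count0, s, N, n_gen, reps, record_gens = NULL) {
  if (s < -1) stop("per-generation selection must satisfy s >= -1")
  counts <- rep.int(as.integer(count0), reps)
  fix_gen <- rep(NA_integer_, reps)
  fix_gen[counts == N] <- 0L
  record <- !is.null(record_gens)
  if (record) {
    record_gens <- as.integer(record_gens)
    freq <- matrix(NA_real_, reps, length(record_gens))
    hit0 <- record_gens == 0L
    if (any(hit0)) freq[, hit0] <- counts / N
  } else {
    freq <- NULL
  }
  active <- counts > 0L & counts < N
  g_max <- if (record) max(n_gen, max(record_gens)) else n_gen
  for (g in seq_len(g_max)) {
    if (g <= n_gen && any(active)) {
      y <- counts[active] / N
      p <- y * (1 + s) / (1 + s * y)
      cnew <- stats::rbinom(length(y), N, p)
      counts[active] <- cnew
      idx <- which(active)
      newly_fixed <- idx[cnew == N]
      fix_gen[newly_fixed] <- g
      active[idx[cnew == 0L | cnew == N]] <- FALSE
    }
    if (record) {
      hit <- record_gens == g
      if (any(hit)) freq[, hit] <- counts / N
    } else if (!any(active)) {
      break
    }
    if (record && !any(active) && all(record_gens <= g)) break
  }
  ## fill records beyond the loop exit (all paths absorbed)
  if (record && anyNA(freq)) {
    for (j in which(colSums(is.na(freq)) > 0)) freq[, j] <- counts / N
  }
  list(fix_gen = fix_gen, censored = active, counts = counts, freq = freq)
}

#' Simulate a single Wright-Fisher path to absorption
#'
#' One forward path of the discrete Wright-Fisher model with genic
#' selection: each generation the derived-allele count is resampled as
#' `Binomial(N, p*)` with post-selection frequency
#' `p* = y (1 + s) / (1 + s y)`.
#'
#' @param y0 initial frequency (rounded to a count on `0..N`).
#' @param s per-generation selection coefficient, `s >= -1`.
#' @param cfg a [wf_config].
#' @return List with `outcome` (`"lost"`, `"fixed"`, or `"censored"`) and
#'   `generation` (absorption generation; `NA` when censored).
#' @export
simulate_wf_path <- function(y0, s, cfg = wf_config()) {
  stopifnot(y0 >= 0, y0 <= 1)
  count0 <- as.integer(round(y0 * cfg$N))
  if (count0 == 0L) return(list(outcome = "lost", generation = 0L))
  r <- wf_sim_batch(count0, s, cfg$N, cfg$n_gen, 1L)
  if (r$censored[1]) {
    list(outcome = "censored", generation = NA_integer_)
  } else if (r$counts[1] == cfg$N) {
    list(outcome = "fixed", generation = r$fix_gen[1])
  } else {
    list(outcome = "lost", generation = NA_integer_)
  }
}

#' Monte-Carlo fixation-time distribution
#'
#' Estimates \eqn{P_y^{\gamma,\kappa}(\tau_1 \le t)} on a time grid by
#' simulating replicate Wright-Fisher paths.  A size-`kappa` population
#' with selection `gamma` is represented by reference-size dynamics with
#' effective selection `gamma * kappa`; a simulated generation `g` then
#' corresponds to evolutionary time `t = kappa * g / N`.  Paths not fixed
#' by the generation horizon are treated as never fixing, which biases the
#' distribution tail downward by at most the reported censoring excess.
#'
#' @param y0 initial frequency.
#' @param regime a [selection_regime] (or numeric gamma with `kappa`).
#' @param time_grid nonnegative evolutionary times.
#' @param cfg a [wf_config].
#' @param kappa size ratio used when `regime` is numeric.
#' @return Object of class `fixation_time_cdf`: list with `time_grid`,
#'   `cdf`, `se`, `y0`, `gamma_eff`, `reps`, `seed`, `censored_frac`.
#' @export
estimate_fixation_cdf <- function(y0, regime, time_grid, cfg = wf_config(),
                                  kappa = 1) {
  regime <- as_regime(regime, if (missing(kappa)) NULL else kappa)
  stopifnot(all(time_grid >= 0))
  gamma_eff <- regime$gamma * regime$kappa
  reps <- reps_fix_for(cfg, gamma_eff)
  seed <- derive_seed(cfg$seed, "fixcdf", signif(gamma_eff, 12), signif(y0, 12))
  set.seed(seed)
  count0 <- as.integer(round(y0 * cfg$N))
  r <- wf_sim_batch(count0, gamma_eff / cfg$N, cfg$N, cfg$n_gen, reps)
  gen_grid <- time_grid * cfg$N / regime$kappa
  fg <- r$fix_gen
  fg[is.na(fg)] <- Inf
  cdf <- vapply(gen_grid, function(g) mean(fg <= g), 0)
  se <- sqrt(cdf * (1 - cdf) / reps)
  ## censoring bound from the diffusion fixation probability
  q <- fixation_prob(count0 / cfg$N, regime)
  fixed_frac <- mean(is.finite(fg))
  cens_excess <- max(0, q - fixed_frac)
  if (q > 0 && cens_excess / q > 0.01 && any(r$censored)) {
    warning(sprintf(
      "censoring may bias the fixation-time CDF: expected fixing mass %.4g, observed %.4g",
      q, fixed_frac))
  }
  structure(list(y0 = y0, gamma_eff = gamma_eff, time_grid = time_grid,
                 cdf = cdf, se = se, reps = reps, seed = seed,
                 censored_frac = mean(r$censored)),
            class = "fixation_time_cdf")
}

#' Monte-Carlo conditional moment of a path functional
#'
#' Estimates \eqn{E_y^{\gamma,\kappa}[f(\xi_t)]} on a time grid by
#' averaging `f` over replicate Wright-Fisher paths (absorbed paths
#' contribute `f(0)` or `f(1)`), using the same size-`kappa` reduction as
#' [estimate_fixation_cdf()].
#'
#' @param f vectorized function on \[0, 1\].
#' @inheritParams estimate_fixation_cdf
#' @return Object of class `moment_estimate`: list with `time_grid`,
#'   `values`, `se`, `y0`, `gamma_eff`, `reps`, `seed`.
#' @export
estimate_moment <- function(f, y0, regime, time_grid, cfg = wf_config(),
                            kappa = 1) {
  regime <- as_regime(regime, if (missing(kappa)) NULL else kappa)
  stopifnot(all(time_grid >= 0))
  gamma_eff <- regime$gamma * regime$kappa
  reps <- cfg$reps_moment
  seed <- derive_seed(cfg$seed, "moment", signif(gamma_eff, 12), signif(y0, 12))
  set.seed(seed)
  count0 <- as.integer(round(y0 * cfg$N))
  gen_grid <- as.integer(round(time_grid * cfg$N / regime$kappa))
  r <- wf_sim_batch(count0, gamma_eff / cfg$N, cfg$N, cfg$n_gen, reps,
                    record_gens = gen_grid)
  fv <- matrix(f(r$freq), nrow = reps)
  values <- colMeans(fv)
  se <- apply(fv, 2, stats::sd) / sqrt(reps)
  ## the t = 0 value is exact
  values[gen_grid == 0L] <- f(count0 / cfg$N)
  se[gen_grid == 0L] <- 0
  structure(list(y0 = y0, gamma_eff = gamma_eff, time_grid = time_grid,
                 values = values, se = se, reps = reps, seed = seed),
            class = "moment_estimate")
}

#' Cached Wright-Fisher engine table
#'
#' Builds (or loads from a TSV cache) a table of Monte-Carlo expectations on
#' the engine frequency grid: either the pairwise-difference moment
#' (`functional = "pw"`) or the fixation-time distribution
#' (`functional = "fix"`).  The cache key encodes the simulation parameters
#' and grids; a JSON sidecar records them in readable form.
#'
#' @param gamma_eff effective scaled selection coefficient.
#' @param ref_times reference-population time grid.
#' @param cfg a [wf_config].
#' @param functional `"pw"` or `"fix"`.
#' @param y_grid frequency grid (default as in [engine_wf()]).
#' @param cache_dir directory for the TSV cache, or `NULL` to skip caching.
#' @return Data frame (`y` plus one column per time) with attribute
#'   `"path"` when cached.
#' @export
wf_table <- function(gamma_eff, ref_times, cfg = wf_config(),
                     functional = c("pw", "fix"), y_grid = NULL,
                     cache_dir = NULL) {
  functional <- match.arg(functional)
  eng <- engine_wf(cfg, y_grid)
  key <- sprintf("wf_%s_N%d_g%d_r%s_s%d_ge%s_h%d",
                 functional, cfg$N, cfg$n_gen,
                 paste0(reps_fix_for(cfg, gamma_eff), "-", cfg$reps_moment),
                 cfg$seed, signif(gamma_eff, 10),
                 derive_seed(0, signif(sum(ref_times), 12),
                             signif(sum(eng$y), 12), length(ref_times)))
  path <- if (!is.null(cache_dir)) file.path(cache_dir, paste0(key, ".tsv"))
  if (!is.null(path) && file.exists(path)) {
    df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
    attr(df, "path") <- path
    return(df)
  }
  f <- if (functional == "fix") f_fix else f_pw
  tab <- eng$moments(f, gamma_eff, ref_times)
  df <- data.frame(y = eng$y, tab$values)
  names(df) <- c("y", sprintf("t_%g", ref_times))
  if (!is.null(path)) {
    write_tsv_provenance(df, path, list(functional = functional,
                                        gamma_eff = gamma_eff))
    jsonlite::write_json(
      list(N = cfg$N, n_gen = cfg$n_gen,
           reps_fix = reps_fix_for(cfg, gamma_eff),
           reps_moment = cfg$reps_moment, seed = cfg$seed,
           gamma_eff = gamma_eff, y_grid = eng$y, ref_times = ref_times),
      sub("\\.tsv$", ".json", path), auto_unbox = TRUE, digits = NA)
    attr(df, "path") <- path
  }
  df
}

#' Finite-population Poisson-field simulation
#'
#' Simulates the whole collection of independent sites at finite `N` and
#' implicit infinite `L`: standing variation is drawn from the equilibrium
#' Poisson intensity \eqn{\theta\,\omega\psi(y)\,dy} of the initial epoch,
#' new mutations enter each generation as a Poisson number of new
#' singletons (rate `theta * kappa(t)` per generation), every segregating
#' site is resampled binomially with selection, and the population size
#' follows the step history (counts are binomially rescaled at each size
#' change).  Returns the site functional \eqn{\langle X_t, f\rangle} and
#' cumulative fixation counts at snapshot times, per replicate.
#'
#' @param params a [model_params] (uses `theta` and `N`).
#' @param history a [size_history].
#' @param regime_or_dfe a [selection_regime] (single selected class, its
#'   `kappa` is ignored), a numeric gamma, or a [gamma_dfe] (selection drawn
#'   per mutation from the DFE, bounded at `gamma_min`).
#' @param t_end end of the simulated window (evolutionary time units).
#' @param cfg a [wf_config]; only `seed` is used.
#' @param snapshot_times times at which the field is evaluated.
#' @param f site functional (default [f_pw]).
#' @param reps independent replicate fields.
#' @param dfe_nodes number of DFE quadrature nodes used to discretize the
#'   selection coefficient of standing variation.
#' @return List with `times`, `f_values` (reps x times), `fixations`
#'   (reps x times, cumulative), `n_segregating` (reps x times), `seed`.
#' @export
simulate_poisson_field <- function(params, history, regime_or_dfe = 0,
                                   t_end, cfg = wf_config(),
                                   snapshot_times = NULL, f = f_pw,
                                   reps = 1, dfe_nodes = 48) {
  stopifnot(t_end > 0)
  if (is.null(snapshot_times)) snapshot_times <- seq(0, t_end, length.out = 11)
  stopifnot(all(snapshot_times >= 0), all(snapshot_times <= t_end))
  theta <- params$theta
  Nref <- as.integer(params$N)
  if (inherits(regime_or_dfe, "gamma_dfe")) {
    qd <- dfe_quadrature(regime_or_dfe, dfe_nodes, truncate = TRUE)
    gam_set <- qd$gamma
    gam_w <- qd$weights / sum(qd$weights)
    draw_gamma <- function(n) {
      u <- stats::rgamma(n, shape = regime_or_dfe$shape,
                         scale = regime_or_dfe$scale)
      -pmin(u, -regime_or_dfe$gamma_min)
    }
  } else {
    g0 <- if (inherits(regime_or_dfe, "selection_regime")) {
      regime_or_dfe$gamma
    } else {
      as.numeric(regime_or_dfe)
    }
    gam_set <- g0
    gam_w <- 1
    draw_gamma <- function(n) rep(g0, n)
  }
  snap_gens <- as.integer(round(snapshot_times * Nref))
  n_gen_total <- as.integer(round(t_end * Nref))
  change_gens <- as.integer(round(history$change_times * Nref))
  f_values <- matrix(0, reps, length(snap_gens))
  fixations <- matrix(0, reps, length(snap_gens))
  n_seg <- matrix(0L, reps, length(snap_gens))
  set.seed(derive_seed(cfg$seed, "field", theta, Nref, t_end))
  kap0 <- history$kappas[1]
  N0 <- as.integer(round(kap0 * Nref))
  ## per-class expected standing-site counts on the initial count grid
  y_init <- (1:(N0 - 1)) / N0
  lam_class <- lapply(seq_along(gam_set), function(j) {
    theta * sfs_intensity(y_init, selection_regime(gam_set[j], kap0)) / N0
  })
  lam_tot_class <- vapply(lam_class, sum, 0) * gam_w
  for (rep_i in seq_len(reps)) {
    ## standing variation from the initial equilibrium intensity
    K <- stats::rpois(1, sum(lam_tot_class))
    if (K > 0 && sum(lam_tot_class) > 0) {
      cls <- sample.int(length(gam_set), K, replace = TRUE,
                        prob = lam_tot_class)
      counts <- integer(K)
      for (j in unique(cls)) {
        sel <- cls == j
        counts[sel] <- sample.int(N0 - 1L, sum(sel), replace = TRUE,
                                  prob = lam_class[[j]])
      }
      gammas <- gam_set[cls]
    } else {
      counts <- integer(0)
      gammas <- numeric(0)
    }
    n_fixed <- 0
    epoch <- 1L
    Ncur <- N0
    kap_cur <- kap0
    hit0 <- snap_gens == 0L
    if (any(hit0)) {
      f_values[rep_i, hit0] <- if (length(counts)) sum(f(counts / N0)) else 0
      fixations[rep_i, hit0] <- 0
      n_seg[rep_i, hit0] <- length(counts)
    }
    for (g in seq_len(max(n_gen_total, 1L))) {
      ## population size change
      while (epoch <= length(change_gens) && g == change_gens[epoch] + 1L) {
        kap_cur <- history$kappas[epoch + 1L]
        Nnew <- as.integer(round(kap_cur * Nref))
        if (length(counts)) {
          counts <- stats::rbinom(length(counts), Nnew, counts / Ncur)
        }
        Ncur <- Nnew
        epoch <- epoch + 1L
      }
      if (length(counts)) {
        y <- counts / Ncur
        ## selection beyond s = -1 is lethal: the allele never reproduces
        s <- pmax(gammas / Nref, -1)
        p <- y * (1 + s) / (1 + s * y)
        counts <- stats::rbinom(length(counts), Ncur, p)
        fixed <- counts == Ncur
        n_fixed <- n_fixed + sum(fixed)
        keep <- counts > 0L & !fixed
        counts <- counts[keep]
        gammas <- gammas[keep]
      }
      ## mutational inflow: theta * kappa new singletons per generation
      m <- stats::rpois(1, theta * kap_cur)
      if (m > 0) {
        counts <- c(counts, rep.int(1L, m))
        gammas <- c(gammas, draw_gamma(m))
      }
      hit <- snap_gens == g
      if (any(hit)) {
        fx <- if (length(counts)) sum(f(counts / Ncur)) else 0
        f_values[rep_i, hit] <- fx
        fixations[rep_i, hit] <- n_fixed
        n_seg[rep_i, hit] <- length(counts)
      }
    }
  }
  list(times = snapshot_times, f_values = f_values, fixations = fixations,
       n_segregating = n_seg, seed = derive_seed(cfg$seed, "field", theta,
                                                 Nref, t_end))
}
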