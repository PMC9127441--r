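## Deterministic engine: finite-difference solution of the backward
## Kolmogorov equation of the Wright-Fisher diffusion with genic selection,
##   du/dt = gamma_eff * y(1-y) u_y + (1/2) y(1-y) u_yy,
## on [0,1] with absorbing boundaries, so that u(y, t) = E_y[f(xi_t)] for
## initial condition u(y, 0) = f(y).  Time stepping is Crank-Nicolson with a
## short implicit-Euler (Rannacher) startup to damp the high-frequency modes
## excited by discontinuous payoffs such as the fixation indicator.
## Advection uses central differences where the mesh Peclet number allows
## and first-order upwinding at nodes where selection dominates, which keeps
## the discrete operator a generator (nonnegative off-diagonals) for
## arbitrarily strong selection.

## Build the interior-operator tridiagonal coefficients for grid step h.
kbe_operator <- function(n_y, gamma_eff) {
  h <- 1 / n_y
  y <- (1:(n_y - 1)) * h        # interior nodes
  a <- gamma_eff * y * (1 - y)  # advection
  D <- 0.5 * y * (1 - y)        # diffusion
  peclet <- abs(a) * h / pmax(D, .Machine$double.xmin)
  upwind <- peclet > 2
  lower <- D / h^2 - a / (2 * h)
  upper <- D / h^2 + a / (2 * h)
  diag  <- -2 * D / h^2
  if (any(upwind)) {
    up <- upwind
    lower[up] <- D[up] / h^2 + pmax(-a[up], 0) / h
    upper[up] <- D[up] / h^2 + pmax(a[up], 0) / h
    diag[up]  <- -(2 * D[up] / h^2 + abs(a[up]) / h)
  }
  list(lower = lower, diag = diag, upper = upper, y = y, h = h)
}

## theta-method matrices for step dt: solve (I - theta*dt*A) u+ =
## (I + (1-theta)*dt*A) u + dt * boundary terms.
kbe_stepper <- function(op, dt, theta = 0.5) {
  n <- length(op$diag)
  tri <- function(scale) {
    Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                       diagonals = list(scale * op$lower[-1],
                                        1 + scale * op$diag,
                                        scale * op$upper[-n]))
  }
  L <- methods::as(tri(-theta * dt), "CsparseMatrix")
  R_diag <- 1 + (1 - theta) * dt * op$diag
  list(lu = Matrix::lu(L),
       R_lower = (1 - theta) * dt * op$lower,
       R_diag = R_diag,
       R_upper = (1 - theta) * dt * op$upper,
       bc_lower = dt * op$lower[1],
       bc_upper = dt * op$upper[n],
       n = n)
}

kbe_step <- function(st, u, bc0, bc1) {
  n <- st$n
  rhs <- st$R_diag * u
  rhs[-n] <- rhs[-n] + st$R_upper[-n] * u[-1]
  rhs[-1] <- rhs[-1] + st$R_lower[-1] * u[-n]
  rhs[1] <- rhs[1] + st$bc_lower * bc0
  rhs[n] <- rhs[n] + st$bc_upper * bc1
  as.numeric(Matrix::solve(st$lu, rhs))
}

#' Solve the backward Kolmogorov equation on a time grid
#'
#' Propagates an initial condition `u(y, 0) = f(y)` under the Wright-Fisher
#' diffusion with effective scaled selection `gamma_eff` (reference-size
#' time units) and returns snapshots `u(y, t) = E_y[f(xi_t)]` at the
#' requested times.  Boundaries are absorbing, so passing the fixation
#' indicator yields the fixation-time distribution
#' `u(y, t) = P_y(tau_1 <= t)`.
#'
#' @param f vectorized initial condition on \[0, 1\], or a numeric vector of
#'   values on the solver grid (length `n_y + 1`).
#' @param gamma_eff effective scaled selection coefficient (`gamma * kappa`
#'   when a size-`kappa` epoch is mapped to reference-size dynamics).
#' @param times nonnegative, increasing snapshot times.
#' @param n_y number of grid intervals (`n_y + 1` grid points).
#' @param dt target time step; steps are shortened to land exactly on
#'   snapshot times.
#' @param rannacher number of implicit-Euler half-step pairs used before
#'   switching to Crank-Nicolson.
#' @param early_exit_tol when the per-unit-time change of the solution
#'   falls below this value the solution is treated as equilibrated and
#'   remaining snapshots are filled with the current state.
#' @return List with `y` (grid of length `n_y + 1`), `times`, and `values`
#'   (matrix, one column per snapshot, including the boundary rows).
#' @export
kbe_solve <- function(f, gamma_eff, times, n_y = 2000, dt = 0.01,
                      rannacher = 2L, early_exit_tol = 1e-12) {
  stopifnot(all(times >= 0), !is.unsorted(times))
  y_full <- (0:n_y) / n_y
  u_full <- if (is.function(f)) f(y_full) else f
  if (length(u_full) != n_y + 1) stop("initial condition has wrong length")
  bc0 <- u_full[1]
  bc1 <- u_full[n_y + 1]
  u <- u_full[2:n_y]
  op <- kbe_operator(n_y, gamma_eff)
  values <- matrix(NA_real_, n_y + 1, length(times))
  out_i <- 1L
  if (length(times) && times[1] == 0) {
    values[, 1L] <- u_full
    out_i <- 2L
  }
  if (out_i > length(times)) {
    return(list(y = y_full, times = times, values = values))
  }
  stepper_cache <- new.env(parent = emptyenv())
  get_stepper <- function(dt_use, theta) {
    key <- sprintf("%a|%g", dt_use, theta)
    if (is.null(stepper_cache[[key]])) {
      stepper_cache[[key]] <- kbe_stepper(op, dt_use, theta)
    }
    stepper_cache[[key]]
  }
  t_now <- 0
  n_ie <- 2L * rannacher   # implicit-Euler half steps remaining
  settled <- FALSE
  for (k in out_i:length(times)) {
    t_target <- times[k]
    if (!settled && t_target > t_now) {
      n_steps <- max(1L, ceiling((t_target - t_now) / dt))
      dt_seg <- (t_target - t_now) / n_steps
      for (s in seq_len(n_steps)) {
        if (n_ie > 0L) {
          st <- get_stepper(dt_seg / 2, 1)
          u_new <- kbe_step(st, kbe_step(st, u, bc0, bc1), bc0, bc1)
          n_ie <- n_ie - 2L
        } else {
          st <- get_stepper(dt_seg, 0.5)
          u_new <- kbe_step(st, u, bc0, bc1)
        }
        delta <- max(abs(u_new - u)) / dt_seg
        u <- u_new
        if (delta < early_exit_tol * max(1, max(abs(u)))) {
          settled <- TRUE
          break
        }
      }
      t_now <- t_target
    }
    values[, k] <- c(bc0, u, bc1)
  }
  list(y = y_full, times = times, values = values)
}

#' Deterministic expectation of a path functional (PDE oracle)
#'
#' Independent numerical value of \eqn{E_y[f(\xi_t)]} for the Wright-Fisher
#' diffusion with selection `gamma` in a population of size `kappa * N`,
#' obtained by solving the backward Kolmogorov equation (no Monte-Carlo
#' noise).  Time in a size-`kappa` epoch is mapped to reference-size
#' dynamics with effective selection `gamma * kappa` and time `t / kappa`.
#'
#' @param f vectorized function on \[0, 1\].
#' @param y0 initial frequency (vector allowed) in \[0, 1\].
#' @param regime a [selection_regime] (or numeric gamma with `kappa`).
#' @param t nonnegative time (scalar).
#' @param kappa size ratio used when `regime` is numeric.
#' @inheritParams kbe_solve
#' @return Expected values at `y0` (linear interpolation on the grid).
#' @examples
#' ## neutral pairwise-difference decay: 2 y (1 - y) e^{-t}
#' pde_oracle(f_pw, 0.5, selection_regime(0, 1), t = 1, n_y = 400)
#' @export
pde_oracle <- function(f, y0, regime, t, kappa = 1, n_y = 2000, dt = 0.005) {
  regime <- as_regime(regime, if (missing(kappa)) NULL else kappa)
  stopifnot(t >= 0, all(y0 >= 0), all(y0 <= 1))
  sol <- kbe_solve(f, regime$gamma * regime$kappa, t / regime$kappa,
                   n_y = n_y, dt = dt)
  stats::approx(sol$y, sol$values[, 1], xout = y0)$y
}
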