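test_that("synonymous diversity follows the piecewise closed form", {
  h <- hist_single(4)
  expect_equal(pi_s_t(h, 1, c(0, 0.3, 1)), c(2, 2, 2))
  expect_equal(pi_s_t(h, 1, 1 + 4), 8 + 2 * (1 - 4) * exp(-1),
               tolerance = 1e-12)
  expect_equal(pi_s_t(h, 1, 1e6), 8, tolerance = 1e-9)
  ## theta scales linearly, continuity at t*
  expect_equal(pi_s_t(h, 2.5, 0.5), 5)
  expect_equal(pi_s_t(h, 1, 1 + 1e-9), 2, tolerance = 1e-6)
})

test_that("the AFS functional reduces to equilibrium when nothing changes", {
  eng <- eng_small()
  h1 <- hist_single(1)
  r <- selection_regime(-2, 1)
  for (t in c(0.5, 3)) {
    ne <- afs_functional(f_pw, r, h1, theta = 1, t = t, engine = eng)
    eq <- equilibrium_functional(f_pw, r, theta = 1, t = t)
    expect_equal(ne$total, eq$total, tolerance = 1e-6)
  }
  ## at t = t* exactly the ancestral equilibrium still applies
  h4 <- hist_single(4)
  at_star <- afs_functional(f_pw, r, h4, 1, t = 1, engine = eng)
  expect_equal(at_star$polymorphic_mass, pi_equilibrium(r, 1),
               tolerance = 1e-8)
})

test_that("neutral AFS functional reproduces the closed-form diversity curve", {
  eng <- engine_pde(n_y = 1000, dt = 0.005)
  for (kap in c(0.25, 4)) {
    h <- hist_single(kap)
    for (t in c(1.2, 2.5, 8)) {
      got <- afs_functional(f_pw, 0, h, 1, t, eng)$polymorphic_mass
      expect_equal(got, pi_s_t(h, 1, t), tolerance = 1e-4)
    }
  }
})

test_that("diversity and fixation series are continuous at the change time", {
  eng <- eng_small()
  dfe <- dfe_std()
  h <- hist_single(4)
  eps <- 1e-7
  ## the transient term at 0+ reconstructs the ancestral equilibrium from
  ## the intensity deficit on the engine grid, so the match is limited by
  ## the grid resolution for the strongly selected DFE nodes
  pin <- pi_n_t(dfe, h, 1, c(1, 1 + eps), eng, n_nodes = 12)
  expect_equal(pin[1], pin[2], tolerance = 1e-2)
  z <- fixations_t(-1, h, 1, c(1, 1 + eps), eng)
  expect_equal(z[1], z[2], tolerance = 1e-2)
})

test_that("pi_n has the stated equilibrium limits and kappa = 1 is constant", {
  eng <- eng_small()
  dfe <- dfe_std()
  qd <- dfe_quadrature(dfe, 16, truncate = TRUE)
  eq_k <- function(kap) {
    sum(qd$weights * vapply(qd$gamma, function(g) {
      pi_equilibrium(selection_regime(g, kap), 1)
    }, 0))
  }
  h <- hist_single(0.25)
  pin <- pi_n_t(dfe, h, 1, c(0.5, 1, 40), eng, n_nodes = 16)
  expect_equal(pin[1], eq_k(1), tolerance = 1e-8)   # ancestral equilibrium
  expect_equal(pin[2], eq_k(1), tolerance = 1e-8)
  expect_equal(pin[3], eq_k(0.25), tolerance = 1e-3)  # new equilibrium
  h1 <- hist_single(1)
  pin1 <- pi_n_t(dfe, h1, 1, c(0.5, 5, 15), eng, n_nodes = 16)
  expect_lt(diff(range(pin1)), 1e-6)
})

test_that("fixations accumulate linearly before the change and stay monotone", {
  eng <- eng_small()
  r <- selection_regime(-1, 1)
  h <- hist_single(4)
  z_pre <- fixations_t(r, h, 1.5, c(0.25, 0.5, 1))
  expect_equal(as.numeric(z_pre),
               1.5 * fixation_rate(r) * c(0.25, 0.5, 1), tolerance = 1e-12)
  tt <- c(0.5, 1, 1.5, 2, 4, 8, 16)
  z <- fixations_t(r, h, 1, tt, eng)
  expect_true(all(diff(as.numeric(z)) > 0))
  ## neutral with kappa = 1: exactly theta * t
  z0 <- fixations_t(0, hist_single(1), 1, tt, eng)
  expect_equal(as.numeric(z0), tt, tolerance = 1e-6)
  ## long-run offset: Z - equilibrium-rate part -> integral of q against the
  ## intensity deficit
  off <- as.numeric(fixations_t(0, h, 1, 60, eng)) - (1 + (60 - 1))
  deficit <- stats::integrate(function(y) y * (2 / y - 8 / y), 0, 1)$value
  expect_equal(off, deficit, tolerance = 1e-3)
})

test_that("omega_bar has the quoted limits and lags the weighted ratio", {
  eng <- eng_small()
  dfe <- dfe_std()
  qd <- dfe_quadrature(dfe, 16, truncate = TRUE)
  e_om <- function(kap) {
    sum(qd$weights * vapply(qd$gamma, function(g) {
      fixation_rate(selection_regime(g, kap))
    }, 0))
  }
  h <- hist_single(4)
  ob <- omega_bar(dfe, h, 1, c(0.5, 1, 2, 5, 120), eng, n_nodes = 16)
  expect_equal(ob[1], e_om(1), tolerance = 1e-10)
  expect_equal(ob[2], e_om(1), tolerance = 1e-10)
  expect_equal(ob[5], e_om(4), tolerance = 5e-3)
  ## the accumulative ratio reacts more slowly than equilibrium weighting
  ow <- omega_weighted(c(2, 5), 1, e_om(1), e_om(4))
  expect_true(all(ob[3:4] >= ow))
  expect_error(omega_bar(dfe, h, 1, 0, eng))
  ## kappa = 1: constant at the ancestral value
  ob1 <- omega_bar(dfe, hist_single(1), 1, c(0.5, 3), eng, n_nodes = 16)
  expect_equal(ob1[1], ob1[2], tolerance = 1e-10)
})

test_that("multi-epoch functional reduces to the single-change form", {
  eng <- eng_small()
  h <- hist_single(4)
  for (f in list(f_pw, f_fix)) {
    for (g in c(0, -1)) {
      a <- afs_functional(f, g, h, 1, 2.5, eng)
      b <- afs_functional_multi(f, g, h, 1, 2.5, eng)
      expect_identical(a$total, b$total)
    }
  }
  ## constant kappa across epochs: polymorphic mass is time-invariant
  hconst <- size_history(1000, c(1, 2), c(2, 2, 2))
  m1 <- afs_functional_multi(f_pw, -1, hconst, 1, 1.5, eng)
  m2 <- afs_functional_multi(f_pw, -1, hconst, 1, 3, eng)
  expect_equal(m1$polymorphic_mass, m2$polymorphic_mass, tolerance = 1e-9)
})

test_that("two-epoch neutral diversity matches the piecewise-exponential oracle", {
  eng <- engine_pde(n_y = 1000, dt = 0.005)
  h2 <- size_history(1000, c(0.5, 1.5), c(1, 4, 0.5))
  for (t in c(0.25, 1, 2, 5)) {
    got <- afs_functional_multi(f_pw, 0, h2, 1, t, eng)$polymorphic_mass
    expect_equal(got, pi_s_t(h2, 1, t), tolerance = 2e-4,
                 info = sprintf("t = %g", t))
  }
})

test_that("the ratio series divides pointwise and propagates uncertainty", {
  pin <- structure(c(0.5, 0.6), se = c(0.01, 0.02))
  ratio <- pin_pis_ratio(pin, c(2, 2))
  expect_equal(as.numeric(ratio), c(0.25, 0.3))
  expect_equal(attr(ratio, "se"), c(0.005, 0.01))
  expect_error(pin_pis_ratio(pin, c(2, 0)))
})

test_that("measure series assembles consistent columns", {
  eng <- eng_small()
  ms <- measure_series(dfe_std(), hist_single(4), 1,
                       times = c(0.5, 1, 2, 6), engine = eng, n_nodes = 8)
  expect_identical(names(ms)[1:10],
                   c("time", "pi_n", "pi_s", "pin_pis", "z_n", "z_s",
                     "omega_bar", "omega_w", "neff_pi", "neff_h"))
  expect_equal(ms$pin_pis, ms$pi_n / ms$pi_s)
  expect_equal(ms$omega_bar, ms$z_n / ms$z_s)
  expect_equal(ms$pi_s, pi_s_t(hist_single(4), 1, ms$time))
  expect_true(all(diff(ms$z_s) > 0))
  prov <- attr(ms, "provenance")
  expect_equal(prov$kappa, 4)
  ## TSV emission round-trips the numbers
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_provenance(ms, path, prov)
  back <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#")
  expect_equal(back$pi_n, ms$pi_n, tolerance = 1e-12)
})
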