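test_that("fixation probability matches the diffusion closed form", {
  ## neutral case is the identity
  y <- c(0, 0.1, 0.4, 0.9, 1)
  expect_equal(fixation_prob(y, selection_regime(0, 1)), y)
  expect_equal(fixation_prob(y, selection_regime(0, 3.7)), y)
  ## absorbing endpoints for any regime
  for (g in c(-250, -3, 0.5)) {
    r <- selection_regime(g, 2)
    expect_equal(fixation_prob(0, r), 0)
    expect_equal(fixation_prob(1, r), 1)
  }
  ## direct evaluation at gamma = -1, kappa = 1
  expect_equal(fixation_prob(0.5, selection_regime(-1, 1)),
               (1 - exp(1)) / (1 - exp(2)), tolerance = 1e-12)
  ## monotone nondecreasing in y
  yy <- seq(0, 1, length.out = 101)
  for (g in c(-1000, -10, -0.5, 2)) {
    expect_true(all(diff(fixation_prob(yy, selection_regime(g, 1))) >= 0))
  }
  expect_error(fixation_prob(1.2, selection_regime(0, 1)))
  expect_error(selection_regime(-1, 0))
})

test_that("fixation rate has the right limits and depends on gamma*kappa only", {
  expect_identical(fixation_rate(selection_regime(0, 0.1)), 1)
  expect_identical(fixation_rate(selection_regime(0, 7)), 1)
  ## continuity at gamma = 0 from both sides
  expect_lt(abs(fixation_rate(selection_regime(1e-11, 1)) - 1), 1e-10)
  expect_lt(abs(fixation_rate(selection_regime(-1e-11, 1)) - 1), 1e-10)
  expect_equal(fixation_rate(selection_regime(-1, 1)), 2 / (exp(2) - 1),
               tolerance = 1e-12)
  ## reparameterization invariance
  for (g in c(-300, -5, -0.01)) {
    for (k in c(0.1, 0.5, 4)) {
      expect_equal(fixation_rate(selection_regime(g, k)),
                   fixation_rate(selection_regime(g * k, 1)))
    }
  }
  ## monotone increasing in gamma, graceful decay for strong selection
  gg <- c(-1000, -100, -10, -1, 0, 1)
  om <- vapply(gg, function(g) fixation_rate(selection_regime(g, 1)), 0)
  expect_true(all(diff(om) > 0))
  expect_true(om[1] >= 0 && om[1] < 1e-200)
})

test_that("spectrum density has the neutral limit and matches direct evaluation", {
  expect_equal(sfs_density(0.5, selection_regime(0, 2)), 8)
  expect_equal(sfs_density(0.5, selection_regime(1e-10, 2)), 8,
               tolerance = 1e-7)
  expect_equal(sfs_density(0.5, selection_regime(-1, 1)),
               (1 - exp(1)) / (-0.25), tolerance = 1e-12)
  ## intensity identity: omega * psi = 2 kappa q(1 - y) / (y (1 - y))
  y <- c(0.01, 0.3, 0.8)
  for (g in c(-20, -0.3)) {
    r <- selection_regime(g, 2)
    expect_equal(sfs_intensity(y, r), fixation_rate(r) * sfs_density(y, r),
                 tolerance = 1e-10)
  }
  expect_error(sfs_density(0, selection_regime(0, 1)))
  expect_error(sfs_density(1, selection_regime(0, 1)))
})

test_that("no overflow or NaN across the simulated selection range", {
  for (g in c(-1000, -750, -300, -50, -1, 0)) {
    for (k in c(0.1, 1, 4)) {
      r <- selection_regime(g, k)
      vals <- c(fixation_rate(r),
                fixation_prob(c(1e-6, 0.5, 1 - 1e-6), r),
                sfs_intensity(c(1e-9, 0.5, 1 - 1e-9), r),
                pi_equilibrium(r, 1))
      expect_true(all(is.finite(vals)), info = sprintf("g=%g k=%g", g, k))
      expect_true(all(vals >= 0))
    }
  }
})

test_that("equilibrium functional separates fixation and polymorphic mass", {
  r0 <- selection_regime(0, 1)
  eq <- equilibrium_functional(f_pw, r0, theta = 1, t = 5)
  expect_equal(eq$fixation_mass, 0)         # f_pw(1) = 0
  expect_equal(eq$polymorphic_mass, 2, tolerance = 1e-9)
  ## fixation indicator: no polymorphic mass, linear fixation accumulation
  r <- selection_regime(-2, 1)
  eqf <- equilibrium_functional(f_fix, r, theta = 1.5, t = 3)
  expect_equal(eqf$polymorphic_mass, 0)
  expect_equal(eqf$fixation_mass, 1.5 * fixation_rate(r) * 3)
  expect_equal(eqf$total, eqf$fixation_mass)
})

test_that("closed-form diversity agrees with quadrature to 1e-8 relative", {
  for (g in c(-100, -10, -1, -0.1)) {
    for (k in c(0.1, 1, 4)) {
      r <- selection_regime(g, k)
      quad <- equilibrium_functional(f_pw, r, theta = 1, t = 0)
      closed <- pi_equilibrium(r, theta = 1)
      expect_equal(quad$polymorphic_mass, closed, tolerance = 1e-8)
    }
  }
  ## neutral and strong-selection limits
  expect_equal(pi_equilibrium(selection_regime(0, 3), 1), 6)
  expect_equal(pi_equilibrium(selection_regime(1e-12, 2), 1.5), 6)
  expect_lt(pi_equilibrium(selection_regime(-1e6, 1), 1), 1e-5)
  expect_equal(pi_equilibrium(selection_regime(-1, 1), 1),
               4 * (1 / (1 - exp(2)) + 0.5), tolerance = 1e-12)
})

test_that("weighted fixation-rate ratio interpolates the two equilibria", {
  expect_equal(omega_weighted(1, 1, 0.9, 0.2), 0.9)
  expect_equal(omega_weighted(2, 1, 1, 0.5), 0.75)
  expect_equal(omega_weighted(1e9, 1, 1, 0.5), 0.5, tolerance = 1e-8)
  expect_error(omega_weighted(0.5, 1, 1, 0.5))
  expect_error(omega_weighted(-1, 1, 1, 0.5))
})
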