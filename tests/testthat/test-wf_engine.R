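test_that("neutral fixation fraction equals the initial frequency", {
  cfg <- wf_config(N = 100, n_gen = 5000, reps_fix = 40000, seed = 2)
  est <- estimate_fixation_cdf(1 / 100, selection_regime(0, 1),
                               c(0, 50), cfg)
  expect_equal(est$cdf[1], 0)
  se <- sqrt(0.01 * 0.99 / est$reps)
  expect_within_se(est$cdf[2], 0.01, se)
})

test_that("selected fixation fractions match the diffusion closed form", {
  cfg <- wf_config(N = 1000, reps_fix = 4000, seed = 5)
  for (g in c(-2, -10)) {
    r <- selection_regime(g, 1)
    est <- estimate_fixation_cdf(0.5, r, c(0, 20), cfg)
    q <- fixation_prob(0.5, r)
    expect_within_se(est$cdf[2], q, sqrt(q * (1 - q) / est$reps))
  }
  ## strong negative selection from high frequency: essentially never fixes
  cfg2 <- wf_config(N = 1000, reps_fix = 2000, seed = 5)
  est2 <- estimate_fixation_cdf(0.9, selection_regime(-500, 1), c(0, 20), cfg2)
  q2 <- fixation_prob(0.9, selection_regime(-500, 1))
  expect_within_se(est2$cdf[2], q2, sqrt(1 / est2$reps))
})

test_that("moment estimates start exactly at f(y0) and decay to zero", {
  cfg <- wf_config(N = 500, reps_moment = 400, seed = 9)
  m <- estimate_moment(f_pw, 0.5, selection_regime(0, 1),
                       c(0, 0.5, 1, 8), cfg)
  expect_identical(m$values[1], f_pw(0.5))
  expect_identical(m$se[1], 0)
  for (j in 2:3) {
    expect_within_se(m$values[j], 0.5 * exp(-m$time_grid[j]), m$se[j],
                     floor = 1e-3)
  }
  expect_lt(m$values[4], 0.02)  # absorbed by t = 8
  expect_true(all(m$values >= 0))
})

test_that("the size-kappa reduction gives identical tables under shared seeds", {
  cfg <- wf_config(N = 300, reps_fix = 500, reps_moment = 200, seed = 13)
  a <- estimate_fixation_cdf(0.4, selection_regime(-1.5, 2), c(0.5, 1, 3), cfg)
  b <- estimate_fixation_cdf(0.4, selection_regime(-3, 1), c(0.25, 0.5, 1.5), cfg)
  expect_identical(a$cdf, b$cdf)
  ma <- estimate_moment(f_pw, 0.4, selection_regime(-1.5, 2), c(1, 2), cfg)
  mb <- estimate_moment(f_pw, 0.4, selection_regime(-3, 1), c(0.5, 1), cfg)
  expect_identical(ma$values, mb$values)
  ## CDF is monotone in t and bounded
  expect_true(all(diff(a$cdf) >= 0))
  expect_true(all(a$cdf >= 0 & a$cdf <= 1))
})

test_that("single-path simulation handles degenerate starts", {
  expect_identical(simulate_wf_path(0, -0.1)$outcome, "lost")
  cfg <- wf_config(N = 50, n_gen = 2000, seed = 1)
  out <- simulate_wf_path(0.5, 0, cfg)
  expect_true(out$outcome %in% c("lost", "fixed"))
  expect_error(estimate_moment(f_pw, 0.5, selection_regime(-2e3, 1),
                               1, wf_config(N = 1000)))  # s < -1
})

test_that("censoring of slow fixations is flagged", {
  ## a horizon far too short for neutral fixation from y0 = 0.5
  cfg <- wf_config(N = 1000, n_gen = 50, reps_fix = 500, seed = 3)
  expect_warning(
    estimate_fixation_cdf(0.5, selection_regime(0, 1), c(0.02, 0.05), cfg),
    "censoring")
})

test_that("Wright-Fisher tables are cached to TSV and reload identically", {
  cache <- withr::local_tempdir()
  cfg <- wf_config(N = 200, n_gen = 2000, reps_fix = 300,
                   reps_moment = 100, seed = 4)
  t1 <- wf_table(-1, c(0.5, 1), cfg, functional = "fix", cache_dir = cache)
  path <- attr(t1, "path")
  expect_true(file.exists(path))
  expect_true(file.exists(sub("\\.tsv$", ".json", path)))
  t2 <- wf_table(-1, c(0.5, 1), cfg, functional = "fix", cache_dir = cache)
  expect_equal(as.matrix(t2), as.matrix(as.data.frame(t1)),
               tolerance = 1e-12, ignore_attr = TRUE)
  sidecar <- jsonlite::read_json(sub("\\.tsv$", ".json", path))
  expect_equal(sidecar$N, 200)
  expect_equal(sidecar$gamma_eff, -1)
})
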