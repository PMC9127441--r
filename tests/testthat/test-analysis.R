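test_that("log-log slope fitting recovers exact power laws", {
  x <- c(100, 250, 1000, 4000)
  fit <- fit_loglog_slope(x, 3.2 * x^(-0.15))
  expect_equal(unname(fit["slope"]), -0.15, tolerance = 1e-10)
  expect_equal(unname(fit["intercept"]), log(3.2), tolerance = 1e-10)
  ## two points: interpolating slope
  f2 <- fit_loglog_slope(c(1, 10), c(2, 1))
  expect_equal(unname(f2["slope"]), log(0.5) / log(10), tolerance = 1e-12)
  expect_error(fit_loglog_slope(c(1, 1), c(1, 2)))
  expect_error(fit_loglog_slope(c(-1, 2), c(1, 2)))
  expect_error(fit_loglog_slope(1, 1))
})

test_that("kappa = 1 rows of the selection-drift table are time-invariant", {
  cfg <- run_config(kappas = 1, times = c(2, 10, 20), n_nodes = 8,
                    engine = eng_small())
  tab <- drift_selection_table(cfg)
  expect_equal(nrow(tab), 3L)
  for (col in c("pin_pis", "omega_bar", "neff_pi", "neff_h")) {
    expect_lt(diff(range(tab[[col]])), 1e-8)
  }
})

test_that("identical configuration and seed give byte-identical TSV output", {
  td <- withr::local_tempdir()
  args <- c("equilibrium", "--out", file.path(td, "a"), "--nodes", "16")
  neqafs_main(args)
  neqafs_main(sub(file.path(td, "a"), file.path(td, "b"), args, fixed = TRUE))
  fa <- file.path(td, "a", "equilibrium_sweep.tsv")
  fb <- file.path(td, "b", "equilibrium_sweep.tsv")
  la <- readLines(fa)
  lb <- readLines(fb)
  ## provenance echoes the differing output paths; the data must be identical
  expect_identical(la[!startsWith(la, "#")], lb[!startsWith(lb, "#")])
})

test_that("the command-line verbs write the documented tables", {
  td <- withr::local_tempdir()
  neqafs_main(c("neff", "--out", td, "--kappas", "4", "--t-grid-step", "2",
                "--t-end", "20"))
  f <- file.path(td, "neff_kappa4.tsv")
  expect_true(file.exists(f))
  df <- utils::read.table(f, header = TRUE, sep = "\t", comment.char = "#")
  expect_identical(names(df), c("time", "neff_pi", "neff_h"))
  expect_equal(df$neff_h[df$time == 20], 80000 / 23, tolerance = 1e-9)
  neqafs_main(c("simulate-field", "--out", td, "--kappas", "1",
                "--N", "100", "--t-end", "2", "--reps", "3"))
  expect_true(file.exists(file.path(td, "field_kappa1.tsv")))
  expect_error(neqafs_main(character()))
  expect_error(neqafs_main("frobnicate"))
})

test_that("configuration files are read and overridden by flags", {
  td <- withr::local_tempdir()
  cfgfile <- file.path(td, "run.yaml")
  writeLines(c("theta: 2.0", "kappas: \"4\"", "t-grid-step: 2",
               "t-end: 4"), cfgfile)
  neqafs_main(c("neff", "--config", cfgfile, "--out", td))
  df <- utils::read.table(file.path(td, "neff_kappa4.tsv"), header = TRUE,
                          sep = "\t", comment.char = "#")
  expect_equal(df$time, c(2, 4))
})
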