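## Shared fixtures: a coarse PDE engine for fast unit tests (the default
## 2000-interval grid is exercised in the oracle and acceptance tests), the
## standard DFE, and frequently used histories.

eng_small <- function() engine_pde(n_y = 400, dt = 0.01)

dfe_std <- function() gamma_dfe(0.15, mean = -2500)

hist_single <- function(kappa, tstar = 1, N = 1000) {
  size_history(N, tstar, c(1, kappa))
}

expect_within_se <- function(estimate, truth, se, n_se = 3, floor = 0) {
  expect_lt(abs(estimate - truth), n_se * pmax(se, floor) + 1e-12)
}
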