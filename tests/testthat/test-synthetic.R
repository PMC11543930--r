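test_that("parametric generation reproduces the closed-form curves and is seed-stable", {
  cfg <- experiment_config(noise = NULL)
  sim <- simulate_experiment(cfg)
  d <- sim$data[sim$data$replicate == 1, ]
  t <- d$time_d
  expect_equal(d$butane_mmol_l, 0.1 + 5.9 * exp(-0.04 * t),
               tolerance = 1e-12)
  expect_equal(d$d13c_butane_permil, -25 + 105 / (1 + exp(-0.08 * (t - 80))),
               tolerance = 1e-12)
  # three technical delta replicates per time point
  expect_equal(nrow(sim$data), 3 * length(t))
  # identical seeds, identical noisy datasets
  cfgN <- experiment_config(seed = 5)
  expect_identical(simulate_experiment(cfgN)$data,
                   simulate_experiment(cfgN)$data)
  # different seeds differ
  expect_false(identical(simulate_experiment(cfgN, seed = 6)$data,
                         simulate_experiment(cfgN)$data))
})

test_that("natural-abundance defaults emulate the unlabeled incubation", {
  cfg <- experiment_config(atom13_dic0 = 0.0112, noise = NULL)
  tru <- default_truth(cfg)
  expect_equal(tru[["d1"]], -15)
  d <- simulate_experiment(cfg)$data
  expect_lt(max(d$d13c_butane_permil), -14.9)
  # the logistic takes a small step above d0 at t = 0
  expect_lt(abs(min(d$d13c_butane_permil) + 25), 0.05)
})

test_that("mechanistic zero-back-flux simulation matches closed-form Rayleigh distillation", {
  cfg <- experiment_config(atom13_dic0 = 0.0112, noise = NULL,
                           mode = "mechanistic")
  sim <- simulate_experiment(cfg, mu_true = 0)
  d <- sim$data[sim$data$replicate == 1, ]
  f12 <- with(sim$truth$states, (4 * A - L) / (4 * A[1] - L[1]))
  closed <- (d$d13c_butane_permil[1] + 1000) * f12^(-0.0025) - 1000
  expect_lt(max(abs(d$d13c_butane_permil - closed)), 1e-3)
  # no fractionation, no drift
  sim1 <- simulate_experiment(cfg, mu_true = 0,
                              constants = isotope_constants(alpha_plus = 1))
  expect_lt(diff(range(sim1$data$d13c_butane_permil)), 1e-6)
})

test_that("carbon and 13C totals are conserved in mechanistic mode", {
  cfg <- experiment_config(noise = NULL, mode = "mechanistic")
  sim <- simulate_experiment(cfg, mu_true = 2e-3)
  st <- sim$truth$states
  ctot <- st$C + 4 * st$A
  c13 <- st$Lc + st$L
  expect_lt(max(abs(ctot / ctot[1] - 1)), 1e-9)
  expect_lt(max(abs(c13 / c13[1] - 1)), 1e-9)
  # assimilation breaks closure by diverting oxidized carbon
  cfg2 <- experiment_config(noise = NULL, mode = "mechanistic",
                            assimilation = 0.04)
  st2 <- simulate_experiment(cfg2, mu_true = 0)$truth$states
  diverted <- 0.04 * 4 * (st2$A[1] - st2$A)
  expect_equal(st2$C + 4 * st2$A + diverted,
               rep(st2$C[1] + 4 * st2$A[1], nrow(st2)), tolerance = 1e-8)
})

test_that("parametric and mechanistic butane trajectories coincide for a first-order net rate", {
  cfg_p <- experiment_config(noise = NULL)
  cfg_m <- experiment_config(noise = NULL, mode = "mechanistic")
  bp <- simulate_experiment(cfg_p)$data$butane_mmol_l
  bm <- simulate_experiment(cfg_m, mu_true = 1e-3)$data$butane_mmol_l
  expect_equal(bp, bm, tolerance = 1e-8)
})

test_that("sulfide tracks consumed butane at the electron-balance ratio and caps at sulfate", {
  expect_equal(sulfide_series(c(6, 3, 0), sulfate0 = 28), c(0, 9.75, 19.5))
  expect_equal(sulfide_series(rep(6, 4), sulfate0 = 28), rep(0, 4))
  # sulfate-limited incubation: sulfide plateaus at the supplied sulfate
  b <- 0.1 + 5.9 * exp(-0.04 * seq(0, 160, 10))
  s <- sulfide_series(b, sulfate0 = 5)
  expect_equal(max(s), 5)
  expect_true(any(s == 5))
  # measured coupling factor is reproduced exactly before noise
  s104 <- sulfide_series(c(6, 0), sulfate0 = 28, coupling_factor = 1.04)
  expect_equal(s104[2] / (3.25 * 6), 1.04)
  expect_error(sulfide_series(c(3, 6)), "non-increasing")
})

test_that("the analytic pipeline recovers a constant true back flux from mechanistic data", {
  # independent oracle: the two-pool ODE with known mu*, fitted blindly
  # by the empirical-curve pipeline
  for (mu0 in c(5e-4, 1e-3, 2e-3, 5e-3)) {
    cfg <- experiment_config(noise = NULL, mode = "mechanistic")
    sim <- simulate_experiment(cfg, mu_true = mu0)
    d <- sim$data[sim$data$replicate == 1, ]
    fit <- backflux(d, times = d$time_d)
    win <- d$butane_mmol_l <= 0.9 * 6 & d$butane_mmol_l >= 0.1 * 6
    mu_hat <- fit$trajectory$mu[match(d$time_d, fit$trajectory$time)]
    err <- abs(mu_hat[win] - mu0) / mu0
    expect_lt(max(err), 0.10)
  }
})

test_that("zero true back flux yields a null estimate below 1e-4", {
  cfg <- experiment_config(noise = NULL, mode = "mechanistic")
  sim <- simulate_experiment(cfg, mu_true = 0)
  d <- sim$data[sim$data$replicate == 1, ]
  fit <- backflux(d, times = seq(5, 150, 5))
  ok <- fit$trajectory$valid
  expect_true(all(abs(fit$trajectory$mu[ok]) < 1e-4))
})
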