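# MCMC unit tests run reduced ensembles; the full-size protocol is
# exercised once in the acceptance suite.

small <- list(chains = 32, steps = 3000, burn_in = 1000, draws = 400)

test_that("the Gaussian log likelihood behaves as a log likelihood should", {
  t <- seq(0, 160, 10)
  y <- 0.1 + 5.9 * exp(-0.04 * t)
  p_true <- c(c0 = 0.1, c1 = 6, lam = 0.04)
  # perfect fit attains the analytic maximum
  expect_equal(log_likelihood(p_true, t, y, sigma = 0.05),
               -length(y) * log(sqrt(2 * pi) * 0.05))
  # truth beats a perturbed candidate on its own data
  p_off <- c(c0 = 0.3, c1 = 5.5, lam = 0.05)
  expect_gt(log_likelihood(p_true, t, y, sigma = 0.05),
            log_likelihood(p_off, t, y, sigma = 0.05))
  # residual-dominated regime: widening sigma raises the likelihood
  y_noisy <- y + 0.5
  expect_gt(log_likelihood(p_true, t, y_noisy, sigma = 0.4),
            log_likelihood(p_true, t, y_noisy, sigma = 0.05))
  # outside the prior support the density vanishes
  pr <- default_priors(alk0 = 6, t_max = 160)
  expect_identical(log_likelihood(c(c0 = -1, c1 = 6, lam = 0.04), t, y,
                                  0.05, priors = pr), -Inf)
})

test_that("the stretch sampler is seed-deterministic and targets a known density", {
  # standard bivariate normal target
  lp <- function(th) -0.5 * rowSums(th^2)
  init <- matrix(rnorm(32 * 2, 0, 0.5), 32, 2)
  a <- stretch_sampler(lp, init, steps = 2000, seed = 99)
  b <- stretch_sampler(lp, init, steps = 2000, seed = 99)
  expect_identical(a$chain, b$chain)
  draws <- matrix(a$chain[501:2000, , ], ncol = 2)
  expect_equal(colMeans(draws), c(0, 0), tolerance = 0.1)
  expect_equal(apply(draws, 2, sd), c(1, 1), tolerance = 0.1)
  expect_gt(a$acceptance, 0.2)
  expect_error(stretch_sampler(function(th) rep(-Inf, nrow(th)), init, 10),
               "non-finite")
})

test_that("posterior sampling recovers the generator and is reproducible", {
  sim <- noise_free_sim(seed = 21)
  ens <- do.call(sample_posterior,
                 c(list(data = sim$data, seed = 31), small))
  expect_true(ens$converged)
  expect_true(all(ens$diagnostics[, "rhat"] < 1.1))
  pm <- colMeans(ens$draws)
  expect_equal(unname(pm), unname(default_params[names(pm)]),
               tolerance = 0.02)
  ens2 <- do.call(sample_posterior,
                  c(list(data = sim$data, seed = 31), small))
  expect_identical(ens$draws, ens2$draws)
})

test_that("posterior medians track the deterministic trajectory on noise-free data", {
  sim <- noise_free_sim(seed = 21)
  ens <- do.call(sample_posterior,
                 c(list(data = sim$data, seed = 31), small))
  tt <- seq(30, 150, 5)
  bands <- posterior_backflux(ens, times = tt)
  det <- back_flux_extent(labeling_setup(),
                          default_params[c("c0", "c1", "lam")],
                          default_params[c("d0", "d1", "d2", "k")],
                          isotope_constants(), tt)
  ok <- det$valid
  expect_lt(max(abs(bands$mu_med[ok] / det$mu[ok] - 1)), 0.05)
  # credible band brackets the deterministic curve almost everywhere
  cover <- mean(det$mu[ok] >= bands$mu_lo95[ok] &
                  det$mu[ok] <= bands$mu_hi95[ok])
  expect_gte(cover, 0.8)
})

test_that("band width on the peak shrinks as the delta likelihood tightens", {
  sim <- noise_free_sim(seed = 21)
  # the peak-width budget is shared with the concentration block, so the
  # shrinkage is monotone only up to Monte-Carlo error
  widths <- vapply(c(2, 1, 0.25), function(sig) {
    ens <- do.call(sample_posterior,
                   c(list(data = sim$data, seed = 31,
                          likelihood = likelihood_spec(sigma_delta = sig)),
                     small))
    b <- posterior_backflux(ens, times = seq(60, 110, 2.5))
    i <- which.max(b$mu_med)
    b$mu_hi95[i] - b$mu_lo95[i]
  }, numeric(1))
  expect_true(all(diff(widths) < 0.05 * widths[-length(widths)]))
  expect_lt(widths[3], widths[1])
})

test_that("posterior means are insensitive to doubling the prior widths", {
  sim <- noise_free_sim(seed = 21)
  pr1 <- default_priors(alk0 = 6, t_max = 160)
  pr2 <- lapply(pr1, function(b) {
    mid <- mean(b); w <- diff(b)
    c(mid - w, mid + w)
  })
  pr2$lam[1] <- 1e-4; pr2$k[1] <- 1e-3; pr2$c0[1] <- 0  # keep positivity
  class(pr2) <- "prior_spec"
  e1 <- do.call(sample_posterior,
                c(list(data = sim$data, seed = 31, priors = pr1), small))
  e2 <- do.call(sample_posterior,
                c(list(data = sim$data, seed = 31, priors = pr2), small))
  sd1 <- apply(e1$draws, 2, sd)
  expect_true(all(abs(colMeans(e1$draws) - colMeans(e2$draws)) <= sd1))
})

test_that("an unconverged ensemble carries a warning into the predictive step", {
  sim <- noise_free_sim(seed = 21)
  ens <- sample_posterior(sim$data, chains = 16, steps = 60, burn_in = 30,
                          draws = 50, seed = 1, init = "prior")
  expect_false(ens$converged)
  expect_warning(posterior_backflux(ens, times = seq(40, 120, 10)),
                 "convergence")
})
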