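p_fo <- default_params[c("c0", "c1", "lam")]
p_lg <- default_params[c("d0", "d1", "d2", "k")]
const <- isotope_constants()
setup <- labeling_setup()

test_that("alkane 13C amount and its closed-form derivative agree with direct evaluation", {
  expect_equal(alkane_13c(p_fo, p_lg, const, 80), 0.015547,
               tolerance = 1e-4)
  # zero pool, zero label
  expect_equal(alkane_13c(c(c0 = 0, c1 = 0 + 1e-300, lam = 0.04), p_lg,
                          const, 80), 0, tolerance = 1e-12)
  # monotone in delta at fixed pool size
  t <- 60
  vals <- vapply(c(-25, 0, 40, 80), function(d1)
    alkane_13c(p_fo, c(d0 = d1, d1 = d1, d2 = 80, k = 0.08), const, t),
    numeric(1))
  expect_true(all(diff(vals) > 0))
  # derivative matches a centred finite difference of the amount
  for (tt in c(20, 80, 130)) {
    h <- 1e-4
    fd <- (alkane_13c(p_fo, p_lg, const, tt + h) -
             alkane_13c(p_fo, p_lg, const, tt - h)) / (2 * h)
    expect_equal(alkane_13c_deriv(p_fo, p_lg, const, tt), fd,
                 tolerance = 1e-6)
  }
  # label-gain term at t = 80 (loss term switched off via lam -> 0 rate)
  gain <- alkane_13c_deriv(p_fo, p_lg, const, 80) +
    const$n * delta_to_frac(80 - 105 / 2) * net_rate(p_fo, 80)
  expect_equal(gain, 3.1411e-5, tolerance = 1e-3)
})

test_that("CO2 pool 13C fraction follows mass conservation", {
  expect_equal(co2_13fraction(setup, p_fo, p_lg, const, 0), 0.98000,
               tolerance = 1e-4)
  expect_equal(co2_13fraction(setup, p_fo, p_lg, const, 80), 0.44010,
               tolerance = 1e-4)
  # natural-abundance mixing: fully consumed alkane, no back flux
  nat <- labeling_setup(atom13_dic0 = 0.0112)
  f_end <- co2_13fraction(nat, c(c0 = 1e-9, c1 = 6, lam = 0.04),
                          c(d0 = -25, d1 = -25, d2 = 80, k = 0.08),
                          const, 1e4)
  expect_equal(f_end, nat$c13_total / nat$c_total, tolerance = 1e-6)
})

test_that("back-flux trajectory reproduces the hand-derived value and the bell shape", {
  tr <- back_flux_extent(setup, p_fo, p_lg, const, 80)
  expect_equal(tr$mu, 1.8375e-3, tolerance = 1e-3)
  expect_equal(tr$f_minus, tr$mu * 4 * tr$v, tolerance = 1e-12)
  expect_equal(tr$f_plus - tr$f_minus / 4, tr$v, tolerance = 1e-12)
  # bell shape over the identifiable window
  tt <- seq(25, 160, 0.5)
  mu <- back_flux_extent(setup, p_fo, p_lg, const, tt)$mu
  i <- which.max(mu)
  expect_gt(i, 1); expect_lt(i, length(mu))
  expect_true(all(diff(mu[1:i]) > 0))
  expect_true(all(diff(mu[i:length(mu)]) < 0))
  expect_true(max(mu) > 1.5e-3 && max(mu) < 2.5e-3)
})

test_that("no isotopic contrast means no measurable back flux", {
  flat <- c(d0 = -25, d1 = -25 + 1e-12, d2 = 80, k = 0.08)
  eq_const <- structure(list(alpha_plus = 1, alpha_minus = 1, n = 4L,
                             r_std = 0.01123720),
                        class = "isotope_constants")
  tr <- back_flux_extent(setup, p_fo, flat, eq_const, seq(10, 100, 10))
  expect_true(all(abs(tr$mu[tr$valid]) < 1e-9))
})

test_that("unidentifiable points are masked rather than extrapolated", {
  # late times: the net rate underflows the tolerance
  tr <- back_flux_extent(setup, p_fo, p_lg, const, c(80, 400, 600),
                         tol = 1e-6)
  expect_true(tr$valid[1])
  expect_false(all(tr$valid))
  expect_true(all(is.na(tr$mu[!tr$valid])))
  expect_error(back_flux_extent(setup, p_fo, p_lg, const, c(500, 600)),
               "no identifiable")
})

test_that("the backflux estimator recovers the generator and exposes a full method suite", {
  sim <- noise_free_sim(seed = 7)
  fit <- backflux(sim$data, times = seq(0, 160, 0.5))
  expect_s3_class(fit, "backflux")
  expect_equal(unname(coef(fit)), unname(default_params), tolerance = 1e-5)
  expect_equal(1000 * fit$mu_peak, 1.8907, tolerance = 1e-3)
  expect_equal(fit$t_peak, 84.5, tolerance = 1e-2)
  # residuals vanish on noise-free data
  expect_lt(max(abs(residuals(fit, "butane"))), 1e-7)
  expect_lt(max(abs(residuals(fit, "delta"))), 1e-6)
  # predictions agree with the generator curves
  expect_equal(predict(fit, times = 40, what = "butane"),
               0.1 + 5.9 * exp(-0.04 * 40), tolerance = 1e-6)
  sm <- summary(fit)
  expect_equal(nrow(sm$coefficients), 7)
  expect_output(print(fit), "peak back flux")
  # simulate() round-trips through the generator deterministically
  s1 <- simulate(fit, nsim = 2, seed = 11)
  s2 <- simulate(fit, nsim = 2, seed = 11)
  expect_identical(s1, s2)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("technical replicates are averaged before fitting", {
  sim <- noise_free_sim(seed = 3)
  d <- sim$data
  d$d13c_butane_permil <- d$d13c_butane_permil +
    c(-1, 0, 1)[d$replicate]  # symmetric spread leaves the mean intact
  fit <- backflux(d)
  expect_equal(coef(fit)[["d1"]], 80, tolerance = 1e-4)
  expect_error(backflux(d[, setdiff(names(d), "d13c_butane_permil")]),
               "d13c_butane_permil")
})
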