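# The isotope mass-balance back-flux model.  From the two fitted
# empirical curves, the amount of 13C in the alkane pool and its time
# derivative follow in closed form; carbon and 13C conservation in the
# closed incubation then give the 13C fraction of the CO2 pool, and the
# isotope balance of the alkane pool yields the fractional back flux
#
#   mu(t) = (d[13C_Alk]/dt + n v alpha+ F_Alk) /
#           (n v (alpha- F_CO2 - alpha+ F_Alk)),
#
# with f- = mu n v (carbon-atom basis) and f+ = (1 + mu) v (alkane
# basis), so that v = f+ - f-/n is the observed net rate.

.coef_of <- function(fit, cls) {
  if (inherits(fit, cls)) fit$coefficients else fit
}

#' Amount of 13C in the alkane pool
#'
#' `[13C_Alk](t) = n F_Alk(t) [Alk](t)`, mmol 13C per litre, with
#' `F_Alk` the atom fraction implied by the fitted logistic delta-13C
#' curve and `[Alk]` the fitted first-order decay curve.
#'
#' @param first A `"first_order_fit"` (or named coefficient vector).
#' @param logistic A `"logistic_fit"` (or named coefficient vector).
#' @param constants An `"isotope_constants"`.
#' @param time Days.
#' @return mmol 13C L^-1.
#' @export
alkane_13c <- function(first, logistic, constants = isotope_constants(),
                       time) {
  p <- .coef_of(first, "first_order_fit")
  q <- .coef_of(logistic, "logistic_fit")
  A <- .first_order_curve(as.list(p), time)
  del <- .logistic_curve(as.list(q), time)
  constants$n * delta_to_frac(del, constants$r_std) * A
}

#' Time derivative of the alkane-pool 13C amount
#'
#' Closed-form derivative of [alkane_13c()]: a label-gain term from the
#' rising delta-13C curve plus a label-loss term from pool shrinkage,
#' `d[13C_Alk]/dt = n [Alk] / (1 + R)^2 * (R_std/1000) * d delta/dt
#'  - n F_Alk v`.
#'
#' @inheritParams alkane_13c
#' @return mmol 13C L^-1 d^-1.
#' @export
alkane_13c_deriv <- function(first, logistic,
                             constants = isotope_constants(), time) {
  p <- .coef_of(first, "first_order_fit")
  q <- .coef_of(logistic, "logistic_fit")
  A <- .first_order_curve(as.list(p), time)
  v <- net_rate(p, time)
  del <- .logistic_curve(as.list(q), time)
  R <- delta_to_ratio(del, constants$r_std)
  u <- exp(-q[["k"]] * (time - q[["d2"]]))
  ddelta_dt <- (q[["d1"]] - q[["d0"]]) * q[["k"]] * u / (1 + u)^2
  gain <- constants$n * A / (1 + R)^2 * (constants$r_std / 1000) * ddelta_dt
  loss <- constants$n * (R / (1 + R)) * v
  gain - loss
}

#' 13C fraction of the CO2 pool by mass conservation
#'
#' In a closed system the totals of carbon and 13C are conserved, so
#' `F_CO2(t) = ([13C]0 - [13C_Alk](t)) / ([C]0 - n [Alk](t))`.
#'
#' @param setup A `"labeling_setup"`.
#' @inheritParams alkane_13c
#' @return Atom fraction of 13C in the CO2 pool.
#' @export
co2_13fraction <- function(setup, first, logistic,
                           constants = isotope_constants(), time) {
  p <- .coef_of(first, "first_order_fit")
  A <- .first_order_curve(as.list(p), time)
  L <- alkane_13c(first, logistic, constants, time)
  co2 <- setup$c_total - constants$n * A
  if (any(co2 <= 1e-9))
    .stopf("CO2 pool vanishes: c_total must exceed n*[Alk](t)")
  (setup$c13_total - L) / co2
}

#' Back-flux trajectory from fitted curves
#'
#' Evaluates the explicit expression for the fractional back flux
#' `mu(t) = f- / (n f_net)` and the associated fluxes at the requested
#' times.  Points where the denominator
#' `n v (alpha- F_CO2 - alpha+ F_Alk)` falls below `tol`
#' (mmol C L^-1 d^-1) or where the net rate is effectively zero are
#' masked (`mu = NA`), because the back flux is unidentifiable there.
#'
#' @param setup A `"labeling_setup"`.
#' @inheritParams alkane_13c
#' @param tol Denominator tolerance, mmol C L^-1 d^-1.
#' @return Data frame of class `"backflux_trajectory"`: `time`, `mu`,
#'   `f_minus` (mmol C L^-1 d^-1), `f_plus`, `v`, `f_net` (both mmol
#'   alkane L^-1 d^-1), `valid`.
#' @export
back_flux_extent <- function(setup, first, logistic,
                             constants = isotope_constants(), time,
                             tol = 1e-6) {
  p <- .coef_of(first, "first_order_fit")
  v <- net_rate(p, time)
  FA <- {
    q <- .coef_of(logistic, "logistic_fit")
    delta_to_frac(.logistic_curve(as.list(q), time), constants$r_std)
  }
  Fc <- co2_13fraction(setup, first, logistic, constants, time)
  dL <- alkane_13c_deriv(first, logistic, constants, time)
  den <- constants$n * v * (constants$alpha_minus * Fc -
                              constants$alpha_plus * FA)
  num <- dL + constants$n * v * constants$alpha_plus * FA
  valid <- abs(den) >= tol & v > tol / constants$n
  mu <- ifelse(valid, num / den, NA_real_)
  if (!any(valid))
    .stopf("no identifiable back flux window: denominator below %g everywhere",
           tol)
  out <- data.frame(time = time, mu = mu,
                    f_minus = mu * constants$n * v,
                    f_plus = (1 + mu) * v,
                    v = v, f_net = v, valid = valid)
  class(out) <- c("backflux_trajectory", "data.frame")
  out
}

#' Fit the back-flux model to a labeling time series
#'
#' The central estimator of the package.  Technical replicates are
#' averaged per time point; the first-order decay curve is fitted to the
#' alkane concentrations and the logistic curve to delta-13C; the two
#' fits are pushed through the isotope mass balance to a back-flux
#' trajectory mu(t).  With `mcmc = TRUE` the seven curve parameters are
#' sampled from their joint posterior by affine-invariant ensemble MCMC
#' (see [sample_posterior()]) and pointwise 95% credible bands on mu(t)
#' are attached.
#'
#' @param data Data frame with columns `time_d`, `butane_mmol_l`,
#'   `d13c_butane_permil` and optionally `replicate` (see
#'   [read_timeseries()]).
#' @param setup A `"labeling_setup"` describing the initial pools.
#' @param constants An `"isotope_constants"`.
#' @param times Evaluation grid for the trajectory (default: 321 points
#'   spanning the data).
#' @param tol Denominator tolerance passed to [back_flux_extent()].
#' @param mcmc Logical: attach posterior uncertainty?
#' @param seed,chains,steps,burn_in,draws MCMC settings (see
#'   [sample_posterior()]).
#' @param priors,likelihood Optional prior and likelihood specifications.
#' @return Object of class `"backflux"` with components `first`,
#'   `logistic`, `trajectory`, `mu_peak`, `t_peak`, `setup`, `constants`,
#'   `data`, and -- when `mcmc = TRUE` -- `ensemble` and `bands`.
#' @examples
#' sim <- simulate_experiment(experiment_config(noise = NULL))
#' fit <- backflux(sim$data)
#' coef(fit)
#' fit$mu_peak
#' @export
backflux <- function(data, setup = labeling_setup(),
                     constants = isotope_constants(), times = NULL,
                     tol = 1e-6, mcmc = FALSE, seed = NULL,
                     chains = 128, steps = 5000, burn_in = 2000,
                     draws = 1000, priors = NULL, likelihood = NULL) {
  avg <- .average_replicates(data)
  first <- fit_first_order(avg$time_d, avg$butane_mmol_l)
  logistic <- fit_logistic(avg$time_d, avg$d13c_butane_permil)
  if (is.null(times))
    times <- seq(min(avg$time_d), max(avg$time_d), length.out = 321)
  traj <- back_flux_extent(setup, first, logistic, constants, times, tol)
  ok <- which(traj$valid)
  i_peak <- ok[which.max(traj$mu[ok])]
  obj <- structure(list(
    first = first, logistic = logistic, trajectory = traj,
    mu_peak = traj$mu[i_peak], t_peak = traj$time[i_peak],
    setup = setup, constants = constants, data = avg, raw_data = data,
    tol = tol
  ), class = "backflux")
  if (mcmc) {
    if (is.null(likelihood)) likelihood <- likelihood_spec()
    ens <- sample_posterior(avg, priors = priors, likelihood = likelihood,
                            chains = chains, steps = steps,
                            burn_in = burn_in, draws = draws, seed = seed,
                            setup = setup)
    obj$ensemble <- ens
    obj$bands <- posterior_backflux(ens, setup, constants, times, tol = tol)
  }
  obj
}

.average_replicates <- function(data) {
  need <- c("time_d", "butane_mmol_l", "d13c_butane_permil")
  missing <- setdiff(need, names(data))
  if (length(missing))
    .stopf("data lacks column(s): %s", paste(missing, collapse = ", "))
  agg <- stats::aggregate(
    data[c("butane_mmol_l", "d13c_butane_permil")],
    by = list(time_d = data$time_d), FUN = mean, na.rm = TRUE)
  agg[order(agg$time_d), , drop = FALSE]
}

#' @export
print.backflux <- function(x, ...) {
  cat("Isotope mass-balance back-flux fit\n")
  cat(sprintf("  alkane decay: c0 = %.4g, c1 = %.4g mmol/L, lambda = %.4g /d\n",
              x$first$coefficients[["c0"]], x$first$coefficients[["c1"]],
              x$first$coefficients[["lam"]]))
  cat(sprintf("  enrichment:   d0 = %.4g, d1 = %.4g permil, d2 = %.4g d, k = %.4g /d\n",
              x$logistic$coefficients[["d0"]], x$logistic$coefficients[["d1"]],
              x$logistic$coefficients[["d2"]], x$logistic$coefficients[["k"]]))
  cat(sprintf("  peak back flux: mu = %.3g (%.2f permil of net rate) at t = %.1f d\n",
              x$mu_peak, 1000 * x$mu_peak, x$t_peak))
  if (!is.null(x$bands))
    cat(sprintf("  95%% band at peak: [%.2f, %.2f] permil\n",
                1000 * x$bands$mu_lo95[which.max(x$bands$mu_med)],
                1000 * x$bands$mu_hi95[which.max(x$bands$mu_med)]))
  invisible(x)
}

#' @export
coef.backflux <- function(object, ...)
  c(object$first$coefficients, object$logistic$coefficients)

#' @export
summary.backflux <- function(object, ...) {
  se <- sqrt(c(diag(object$first$vcov), diag(object$logistic$vcov)))
  tab <- data.frame(estimate = coef(object), std_error = se)
  out <- list(coefficients = tab, mu_peak = object$mu_peak,
              t_peak = object$t_peak,
              n_points = nrow(object$data),
              diagnostics = object$ensemble$diagnostics)
  class(out) <- "summary.backflux"
  out
}

#' @export
print.summary.backflux <- function(x, ...) {
  cat("Back-flux model summary\n\nCurve parameters:\n")
  print(signif(x$coefficients, 5))
  cat(sprintf("\nPeak back flux mu = %.3g at t = %.1f d (%d time points)\n",
              x$mu_peak, x$t_peak, x$n_points))
  if (!is.null(x$diagnostics)) {
    cat("\nMCMC diagnostics (integrated autocorrelation time, split R-hat):\n")
    print(signif(x$diagnostics, 4))
  }
  invisible(x)
}

#' @export
predict.backflux <- function(object, times = object$trajectory$time,
                             what = c("mu", "butane", "delta",
                                      "trajectory"), ...) {
  what <- match.arg(what)
  switch(what,
    mu = back_flux_extent(object$setup, object$first, object$logistic,
                          object$constants, times, object$tol)$mu,
    butane = predict(object$first, times),
    delta = predict(object$logistic, times),
    trajectory = back_flux_extent(object$setup, object$first,
                                  object$logistic, object$constants,
                                  times, object$tol))
}

#' @export
residuals.backflux <- function(object,
                               which = c("butane", "delta"), ...) {
  which <- match.arg(which)
  if (which == "butane") object$first$residuals else
    object$logistic$residuals
}

#' @export
simulate.backflux <- function(object, nsim = 1, seed = NULL, ...) {
  cfg <- experiment_config(
    alk0 = object$setup$alk0, dic0 = object$setup$dic0,
    atom13_dic0 = object$setup$atom13_dic0,
    delta0_alk = object$setup$delta0_alk,
    schedule = object$data$time_d, seed = seed)
  .with_seed(seed, lapply(seq_len(nsim), function(i)
    simulate_experiment(cfg, params = coef(object), seed = NULL)$data))
}

#' @export
plot.backflux <- function(x, ...) {
  op <- par(mfrow = c(3, 1), mar = c(4, 4.2, 1.5, 1))
  on.exit(par(op))
  tt <- x$trajectory$time
  plot(x$data$time_d, x$data$butane_mmol_l, xlab = "time (d)",
       ylab = "butane (mmol/L)", pch = 19)
  lines(tt, predict(x$first, tt), col = "steelblue", lwd = 2)
  plot(x$data$time_d, x$data$d13c_butane_permil, xlab = "time (d)",
       ylab = expression(delta^13 * C ~ "(permil)"), pch = 19)
  lines(tt, predict(x$logistic, tt), col = "steelblue", lwd = 2)
  plot(tt, 1000 * x$trajectory$mu, type = "l", lwd = 2,
       xlab = "time (d)", ylab = "back flux (permil of net rate)")
  if (!is.null(x$bands)) {
    polygon(c(x$bands$time, rev(x$bands$time)),
            1000 * c(x$bands$mu_lo95, rev(x$bands$mu_hi95)),
            col = adjustcolor("steelblue", 0.3), border = NA)
    lines(tt, 1000 * x$trajectory$mu, lwd = 2)
  }
  invisible(x)
}
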