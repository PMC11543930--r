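# Empirical curve fits of the mass-balance model: first-order substrate
# decay (three parameters) and logistic delta-13C enrichment (four
# parameters).  Both use Levenberg-Marquardt least squares with analytic
# Jacobians and the initial-guess recipes stated in the documentation.

.first_order_curve <- function(p, t)
  p[["c0"]] + (p[["c1"]] - p[["c0"]]) * exp(-p[["lam"]] * t)

.logistic_curve <- function(p, t)
  p[["d0"]] + (p[["d1"]] - p[["d0"]]) / (1 + exp(-p[["k"]] * (t - p[["d2"]])))

#' Fit the first-order alkane decay curve
#'
#' Fits `[Alk](t) = c0 + (c1 - c0) exp(-lambda t)`: `c1` is the initial
#' pool, `c0` the non-reacting floor and `lambda` the first-order rate
#' constant (d^-1).  Starting values follow the stated recipe (c1 from
#' the first observation, c0 from the last, lambda from a log-linear
#' regression of the excess above the floor); optimisation is
#' Levenberg-Marquardt with analytic Jacobian and parameter tolerance
#' 1e-10.
#'
#' @param time Days.
#' @param conc Alkane concentration, mmol L^-1 (positive).
#' @return Object of class `"first_order_fit"`: `coefficients`
#'   (c0, c1, lam), `vcov`, `residuals`, `data`.
#' @examples
#' t <- seq(0, 160, 10)
#' y <- 0.1 + 5.9 * exp(-0.04 * t)
#' coef(fit_first_order(t, y))
#' @export
fit_first_order <- function(time, conc) {
  stopifnot(length(time) == length(conc))
  if (length(time) < 4) .stopf("need at least 4 time points")
  .assert_numeric(conc, "conc", positive = TRUE)
  ord <- order(time); time <- time[ord]; conc <- conc[ord]
  if (diff(range(conc)) < 1e-10 * max(conc))
    .stopf(paste("concentration series is constant: no decay to fit",
                 "(degenerate case)"))
  c1_0 <- conc[1]
  c0_0 <- min(conc[length(conc)], 0.99 * min(conc))
  excess <- pmax(conc - c0_0, 1e-12)
  lam_0 <- max(1e-4, -unname(coef(lm(log(excess) ~ time))[2]))
  res_fn <- function(p) conc - .first_order_curve(p, time)
  jac_fn <- function(p) {
    e <- exp(-p[["lam"]] * time)
    -cbind(c0 = 1 - e, c1 = e, lam = -(p[["c1"]] - p[["c0"]]) * time * e)
  }
  fit <- minpack.lm::nls.lm(
    par = c(c0 = c0_0, c1 = c1_0, lam = lam_0), fn = res_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxiter = 500))
  p <- fit$par
  if (fit$info %in% c(0, 9) || !is.finite(p[["lam"]]) || p[["lam"]] <= 0)
    .stopf(paste("first-order fit did not converge (lambda <= 0 or",
                 "iteration failure); a near-constant series has no",
                 "identifiable decay"))
  m <- length(conc)
  dof <- max(m - 3, 1)
  s2 <- sum(fit$fvec^2) / dof
  J <- -jac_fn(p)
  vc <- tryCatch(s2 * solve(crossprod(J)),
                 error = function(e) matrix(NA_real_, 3, 3))
  dimnames(vc) <- list(names(p), names(p))
  structure(list(coefficients = unlist(p), vcov = vc,
                 residuals = fit$fvec, data = list(time = time, conc = conc)),
            class = "first_order_fit")
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat("First-order decay fit: c0 + (c1 - c0) exp(-lambda t)\n")
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' @export
predict.first_order_fit <- function(object, time = object$data$time, ...)
  .first_order_curve(as.list(object$coefficients), time)

#' Net alkane consumption rate from a first-order fit
#'
#' `v(t) = -d[Alk]/dt = lambda ([Alk](t) - c0)
#'       = lambda (c1 - c0) exp(-lambda t)`, mmol L^-1 d^-1.
#'
#' @param fit A `"first_order_fit"` (or a named vector with c0, c1, lam).
#' @param time Days.
#' @return Non-negative rates.
#' @export
net_rate <- function(fit, time) {
  p <- if (inherits(fit, "first_order_fit")) fit$coefficients else fit
  unname(p[["lam"]] * (p[["c1"]] - p[["c0"]]) * exp(-p[["lam"]] * time))
}

#' Fit the logistic delta-13C enrichment curve
#'
#' Fits `delta(t) = d0 + (d1 - d0) / (1 + exp(-k (t - d2)))`: `d0` and
#' `d1` are the initial and plateau compositions (permil), `d2` the
#' half-rise time (d) and `k` the steepness (d^-1).  Starting values:
#' d0 from the first observation, d1 from the last, d2 from the time
#' nearest the half rise, k from the finite-difference slope there.  A
#' flat series cannot identify d2 or k and is returned with
#' `degenerate = TRUE` rather than an error.
#'
#' @param time Days.
#' @param delta delta-13C, permil.
#' @return Object of class `"logistic_fit"`: `coefficients`
#'   (d0, d1, d2, k), `vcov`, `residuals`, `degenerate`, `data`.
#' @examples
#' t <- seq(0, 160, 10)
#' d <- -25 + 105 / (1 + exp(-0.08 * (t - 80)))
#' coef(fit_logistic(t, d))
#' @export
fit_logistic <- function(time, delta) {
  stopifnot(length(time) == length(delta))
  if (length(time) < 5) .stopf("need at least 5 time points")
  ord <- order(time); time <- time[ord]; delta <- delta[ord]
  if (diff(range(delta)) < 1e-8) {
    p <- c(d0 = mean(delta), d1 = mean(delta), d2 = mean(time), k = 0.05)
    return(structure(list(coefficients = p,
                          vcov = matrix(NA_real_, 4, 4,
                                        dimnames = list(names(p), names(p))),
                          residuals = delta - mean(delta),
                          degenerate = TRUE,
                          data = list(time = time, delta = delta)),
                     class = "logistic_fit"))
  }
  d0_0 <- delta[1]; d1_0 <- delta[length(delta)]
  half <- (d0_0 + d1_0) / 2
  i_half <- which.min(abs(delta - half))
  d2_0 <- time[i_half]
  slope <- if (i_half > 1 && i_half < length(time))
    (delta[i_half + 1] - delta[i_half - 1]) /
      (time[i_half + 1] - time[i_half - 1])
  else diff(range(delta)) / diff(range(time))
  k_0 <- max(1e-3, abs(4 * slope / (d1_0 - d0_0)))
  res_fn <- function(p) delta - .logistic_curve(p, time)
  jac_fn <- function(p) {
    u <- exp(-p[["k"]] * (time - p[["d2"]]))
    s <- 1 / (1 + u)
    dd <- p[["d1"]] - p[["d0"]]
    -cbind(d0 = 1 - s, d1 = s,
           d2 = -dd * s^2 * u * p[["k"]],
           k = dd * s^2 * u * (time - p[["d2"]]))
  }
  fit <- minpack.lm::nls.lm(
    par = c(d0 = d0_0, d1 = d1_0, d2 = d2_0, k = k_0),
    fn = res_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxiter = 1000))
  p <- fit$par
  if (fit$info %in% c(0, 9) || !is.finite(p[["k"]]) || p[["k"]] <= 0)
    .stopf(paste("logistic fit did not converge; series range %.2f permil,",
                 "%d points -- check for monotone S-shaped dynamics"),
           diff(range(delta)), length(delta))
  m <- length(delta)
  s2 <- sum(fit$fvec^2) / max(m - 4, 1)
  J <- -jac_fn(p)
  vc <- tryCatch(s2 * solve(crossprod(J)),
                 error = function(e) matrix(NA_real_, 4, 4))
  dimnames(vc) <- list(names(p), names(p))
  structure(list(coefficients = unlist(p), vcov = vc, residuals = fit$fvec,
                 degenerate = abs(p[["d1"]] - p[["d0"]]) < 1e-6,
                 data = list(time = time, delta = delta)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic enrichment fit: d0 + (d1 - d0)/(1 + exp(-k (t - d2)))\n")
  print(signif(x$coefficients, 6))
  if (isTRUE(x$degenerate)) cat("  (degenerate: flat series)\n")
  invisible(x)
}

#' @export
predict.logistic_fit <- function(object, time = object$data$time, ...)
  .logistic_curve(as.list(object$coefficients), time)
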