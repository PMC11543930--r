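# Affine-invariant ensemble MCMC (Goodman-Weare stretch move) for the
# seven empirical curve parameters, sampled as two independent blocks
# mirroring the two sub-models: (c0, c1, lambda) against the
# concentration series and (d0, d1, d2, k) against the delta-13C series.

#' Uniform prior bounds for the curve parameters
#'
#' Wide, positivity-respecting defaults: `c0` in [0, alk0], `c1` in
#' [0.5 alk0, 2 alk0], `lambda` in [1e-4, 1] d^-1, `d0` in [-60, 20]
#' permil, `d1` in [-60, 1000] permil, `d2` in [0, 2 t_max] d, `k` in
#' [1e-3, 1] d^-1.
#'
#' @param alk0 Initial alkane (mmol L^-1) anchoring the concentration
#'   bounds.
#' @param t_max Last observation time (d) anchoring the half-rise bound.
#' @return List of class `"prior_spec"`; one `c(low, high)` per
#'   parameter.
#' @export
default_priors <- function(alk0 = 6, t_max = 160) {
  structure(list(
    c0 = c(0, alk0), c1 = c(0.5 * alk0, 2 * alk0), lam = c(1e-4, 1),
    d0 = c(-60, 20), d1 = c(-60, 1000), d2 = c(0, 2 * t_max),
    k = c(1e-3, 1)
  ), class = "prior_spec")
}

#' Gaussian likelihood specification
#'
#' The likelihood of each series is Gaussian in the model-data residuals.
#' For the concentration series the standard deviation is
#' `sigma_conc * mean(observed)` (relative, default 5%); for the
#' delta-13C series it is `sigma_delta` permil (default 1).
#'
#' @param sigma_conc Relative standard deviation on concentrations.
#' @param sigma_delta Absolute standard deviation on delta-13C, permil.
#' @return List of class `"likelihood_spec"`.
#' @export
likelihood_spec <- function(sigma_conc = 0.05, sigma_delta = 1) {
  .assert_numeric(sigma_conc, "sigma_conc", positive = TRUE)
  .assert_numeric(sigma_delta, "sigma_delta", positive = TRUE)
  structure(list(sigma_conc = sigma_conc, sigma_delta = sigma_delta),
            class = "likelihood_spec")
}

#' Gaussian log likelihood of curve parameters
#'
#' Sum of Gaussian log densities of the observations around the model
#' curve (the squared-error exponent enters negatively).  Parameters
#' outside the prior support score `-Inf`.
#'
#' @param params Named vector: either (c0, c1, lam) or (d0, d1, d2, k).
#' @param time,y Observed series.
#' @param sigma Standard deviation of the error term (absolute units of
#'   `y`).
#' @param priors A `"prior_spec"` for support checks (optional).
#' @return Log likelihood (scalar).
#' @export
log_likelihood <- function(params, time, y, sigma, priors = NULL) {
  if (!is.null(priors)) {
    for (pn in intersect(names(params), names(priors))) {
      b <- priors[[pn]]
      if (params[[pn]] < b[1] || params[[pn]] > b[2]) return(-Inf)
    }
  }
  mu <- if (all(c("c0", "c1", "lam") %in% names(params)))
    .first_order_curve(as.list(params), time)
  else if (all(c("d0", "d1", "d2", "k") %in% names(params)))
    .logistic_curve(as.list(params), time)
  else .stopf("params must name a first-order or logistic parameter set")
  sum(stats::dnorm(y, mu, sigma, log = TRUE))
}

# vectorised block log probability: rows of `th` are walkers
.block_logprob <- function(th, curve, time, y, sigma, lo, hi) {
  inside <- rep(TRUE, nrow(th))
  for (j in seq_len(ncol(th)))
    inside <- inside & th[, j] >= lo[j] & th[, j] <= hi[j]
  lp <- rep(-Inf, nrow(th))
  if (any(inside)) {
    pred <- curve(th[inside, , drop = FALSE], time)
    r2 <- colSums((t(pred) - y)^2)
    m <- length(y)
    lp[inside] <- -m * log(sqrt(2 * pi) * sigma) - r2 / (2 * sigma^2)
  }
  lp
}

# row-wise curve evaluators: theta matrix -> matrix walkers x time
.fo_rows <- function(th, t)
  th[, 1] + (th[, 2] - th[, 1]) * exp(-th[, 3] %o% t)

.lg_rows <- function(th, t) {
  e <- exp(-th[, 4] * outer(rep(1, nrow(th)), t) +
             th[, 4] * th[, 3])
  th[, 1] + (th[, 2] - th[, 1]) / (1 + e)
}

#' Affine-invariant ensemble sampler (stretch move)
#'
#' The Goodman-Weare stretch move: each walker proposes a jump along the
#' line towards a randomly chosen partner from the complementary half of
#' the ensemble, with scale `z` drawn from g(z) proportional to
#' 1/sqrt(z) on [1/a, a].  Updates alternate over the two half-ensembles
#' and are vectorised within each half.
#'
#' @param log_prob Function taking a matrix (walkers x dim) and returning
#'   a vector of log probabilities.
#' @param init Matrix of initial walker positions (walkers x dim); the
#'   walker count must be even and at least twice the dimension.
#' @param steps Number of ensemble cycles.
#' @param a Stretch scale (default 2).
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @return List with `chain` (array steps x walkers x dim),
#'   `log_prob` (steps x walkers) and `acceptance` (mean rate).
#' @export
stretch_sampler <- function(log_prob, init, steps, a = 2, seed = NULL) {
  nw <- nrow(init); d <- ncol(init)
  if (nw %% 2L != 0L) .stopf("walker count must be even")
  if (nw < 2 * d) .stopf("need at least %d walkers for dimension %d", 2 * d, d)
  .with_seed(seed, {
    cur <- init
    lp <- log_prob(cur)
    if (all(!is.finite(lp)))
      .stopf(paste("log probability is non-finite at every initial walker;",
                   "widen the priors or the initial positions"))
    chain <- array(NA_real_, c(steps, nw, d),
                   dimnames = list(NULL, NULL, colnames(init)))
    lps <- matrix(NA_real_, steps, nw)
    half <- list(seq_len(nw / 2), nw / 2 + seq_len(nw / 2))
    acc <- 0L
    for (s in seq_len(steps)) {
      for (h in 1:2) {
        idx <- half[[h]]; oth <- half[[3 - h]]
        z <- ((a - 1) * runif(length(idx)) + 1)^2 / a
        partner <- oth[sample.int(length(oth), length(idx), replace = TRUE)]
        prop <- cur[partner, , drop = FALSE] +
          z * (cur[idx, , drop = FALSE] - cur[partner, , drop = FALSE])
        lp_new <- log_prob(prop)
        log_r <- (d - 1) * log(z) + lp_new - lp[idx]
        take <- log(runif(length(idx))) < log_r
        take[!is.finite(lp_new)] <- FALSE
        cur[idx[take], ] <- prop[take, , drop = FALSE]
        lp[idx[take]] <- lp_new[take]
        acc <- acc + sum(take)
      }
      chain[s, , ] <- cur
      lps[s, ] <- lp
    }
    list(chain = chain, log_prob = lps,
         acceptance = acc / (steps * nw))
  })
}

# integrated autocorrelation time: per-walker autocorrelation functions
# averaged over the ensemble, then Sokal-windowed with c = 5
.integrated_act <- function(mat) {  # steps x walkers
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
  n <- nrow(mat)
  lag_max <- min(n - 2, 1000)
  keep <- apply(mat, 2, sd) > 0
  if (!any(keep)) return(1)
  acfs <- vapply(which(keep), function(w)
    stats::acf(mat[, w], lag.max = lag_max, plot = FALSE,
               demean = TRUE)$acf[, 1, 1],
    numeric(lag_max + 1))
  rho <- rowMeans(acfs)
  tau <- 2 * cumsum(rho) - 1
  w <- which(seq_along(tau) >= 5 * tau)
  if (length(w)) tau[w[1]] else tau[length(tau)]
}

# split-chain scale reduction (Gelman-Rubin) over walkers, halves split
.split_rhat <- function(mat) {  # steps x walkers
  n2 <- floor(nrow(mat) / 2)
  chains <- cbind(mat[seq_len(n2), , drop = FALSE],
                  mat[n2 + seq_len(n2), , drop = FALSE])
  m <- ncol(chains); n <- nrow(chains)
  means <- colMeans(chains)
  vars <- apply(chains, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Sample the posterior of the seven curve parameters
#'
#' Runs two independent stretch-move ensembles -- (c0, c1, lambda) on the
#' concentration series and (d0, d1, d2, k) on the delta-13C series --
#' with uniform priors and Gaussian likelihoods, discards burn-in, checks
#' convergence (integrated autocorrelation time and split-chain scale
#' reduction) and retains a uniform subsample of the post-burn-in draws.
#'
#' @param data Data frame with `time_d`, `butane_mmol_l`,
#'   `d13c_butane_permil` (technical replicates averaged beforehand or
#'   by [backflux()]).
#' @param priors A `"prior_spec"`; default derived from the data range.
#' @param likelihood A `"likelihood_spec"`.
#' @param chains Number of walkers (default 128).
#' @param steps Ensemble cycles per walker (default 5000).
#' @param burn_in Cycles discarded before drawing (default 2000).
#' @param draws Posterior draws retained (default 1000).
#' @param seed RNG seed for reproducibility.
#' @param init `"ball"` (default) starts the walkers in a small Gaussian
#'   ball around the least-squares estimate -- standard practice for
#'   stretch-move ensembles, whose walker updates interpolate between
#'   ensemble members and therefore mix poorly when no walker starts
#'   near a narrow posterior basin.  `"prior"` draws the walkers
#'   uniformly from the priors instead.
#' @param setup Optional `"labeling_setup"` used only to anchor default
#'   priors at the nominal initial alkane.
#' @return Object of class `"posterior_ensemble"`: `draws` (matrix draws
#'   x 7), `diagnostics` (per-parameter tau and R-hat), `acceptance`,
#'   `converged`, and the settings.
#' @export
sample_posterior <- function(data, priors = NULL,
                             likelihood = likelihood_spec(),
                             chains = 128, steps = 5000, burn_in = 2000,
                             draws = 1000, seed = NULL,
                             init = c("ball", "prior"), setup = NULL) {
  init <- match.arg(init)
  avg <- .average_replicates(data)
  if (burn_in >= steps) .stopf("burn_in must be smaller than steps")
  if (is.null(priors))
    priors <- default_priors(
      alk0 = if (is.null(setup)) max(avg$butane_mmol_l) else setup$alk0,
      t_max = max(avg$time_d))
  sigma_c <- likelihood$sigma_conc * mean(avg$butane_mmol_l)
  sigma_d <- likelihood$sigma_delta

  run_block <- function(par_names, curve, y, sigma, center, block_seed) {
    lo <- vapply(priors[par_names], `[`, numeric(1), 1)
    hi <- vapply(priors[par_names], `[`, numeric(1), 2)
    lp_fn <- function(th) .block_logprob(th, curve, avg$time_d, y, sigma,
                                         lo, hi)
    start <- .with_seed(block_seed, {
      k <- length(par_names)
      m <- if (init == "prior" || is.null(center)) {
        matrix(runif(chains * k, rep(lo, each = chains),
                     rep(hi, each = chains)), nrow = chains)
      } else {
        scale <- pmax(abs(center) * 0.02, 1e-3 * (hi - lo))
        jit <- matrix(rnorm(chains * k, rep(center, each = chains),
                            rep(scale, each = chains)), nrow = chains)
        # keep the ball inside the prior support
        pmin(pmax(jit, rep(lo, each = chains)), rep(hi, each = chains))
      }
      colnames(m) <- par_names
      m
    })
    fit <- stretch_sampler(lp_fn, start, steps, seed = block_seed + 1L)
    post <- fit$chain[(burn_in + 1):steps, , , drop = FALSE]
    diag <- t(vapply(seq_along(par_names), function(j) {
      c(tau = .integrated_act(post[, , j]),
        rhat = .split_rhat(post[, , j]))
    }, numeric(2)))
    rownames(diag) <- par_names
    list(post = post, diag = diag, acceptance = fit$acceptance)
  }

  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  center_c <- if (init == "ball")
    tryCatch(fit_first_order(avg$time_d, avg$butane_mmol_l)$coefficients,
             error = function(e) NULL)
  center_d <- if (init == "ball")
    tryCatch(fit_logistic(avg$time_d, avg$d13c_butane_permil)$coefficients,
             error = function(e) NULL)
  b1 <- run_block(c("c0", "c1", "lam"), .fo_rows, avg$butane_mmol_l,
                  sigma_c, center_c,
                  if (is.null(base_seed)) NULL else base_seed)
  b2 <- run_block(c("d0", "d1", "d2", "k"), .lg_rows,
                  avg$d13c_butane_permil, sigma_d, center_d,
                  if (is.null(base_seed)) NULL else base_seed + 1000L)

  pick <- .with_seed(if (is.null(base_seed)) NULL else base_seed + 2000L, {
    n_avail <- dim(b1$post)[1] * dim(b1$post)[2]
    sample.int(n_avail, min(draws, n_avail))
  })
  flatten <- function(post) {
    d <- dim(post)
    matrix(post, d[1] * d[2], d[3],
           dimnames = list(NULL, dimnames(post)[[3]]))
  }
  dr <- cbind(flatten(b1$post)[pick, , drop = FALSE],
              flatten(b2$post)[pick, , drop = FALSE])
  diagn <- rbind(b1$diag, b2$diag)
  structure(list(
    draws = dr, diagnostics = diagn,
    acceptance = c(conc = b1$acceptance, delta = b2$acceptance),
    converged = all(diagn[, "rhat"] < 1.1) &&
      all(50 * diagn[, "tau"] <= steps),
    chains = chains, steps = steps, burn_in = burn_in, seed = seed,
    likelihood = likelihood, priors = priors
  ), class = "posterior_ensemble")
}

#' @export
print.posterior_ensemble <- function(x, ...) {
  cat(sprintf(
    "Posterior ensemble: %d draws from %d walkers x %d cycles (burn-in %d)\n",
    nrow(x$draws), x$chains, x$steps, x$burn_in))
  cat("Posterior means:\n")
  print(signif(colMeans(x$draws), 5))
  cat("Diagnostics:\n")
  print(signif(x$diagnostics, 4))
  cat(sprintf("acceptance: %.2f / %.2f; converged: %s\n",
              x$acceptance[1], x$acceptance[2], x$converged))
  invisible(x)
}

#' Posterior predictive back-flux trajectory
#'
#' Evaluates mu(t) for every posterior draw and reports the pointwise
#' median and central 95% band.  A warning is attached when the ensemble
#' failed its convergence checks.
#'
#' @param ensemble A `"posterior_ensemble"`.
#' @param setup A `"labeling_setup"`.
#' @param constants An `"isotope_constants"`.
#' @param times Evaluation grid (d).
#' @param tol Denominator tolerance (see [back_flux_extent()]).
#' @return Data frame: `time`, `mu_med`, `mu_lo95`, `mu_hi95`,
#'   `n_valid` (draws unmasked per time point).
#' @export
posterior_backflux <- function(ensemble, setup = labeling_setup(),
                               constants = isotope_constants(),
                               times = seq(0, 160, by = 0.5),
                               tol = 1e-6) {
  stopifnot(inherits(ensemble, "posterior_ensemble"))
  if (!isTRUE(ensemble$converged))
    warning("posterior ensemble failed convergence checks; bands may be unreliable",
            call. = FALSE)
  dr <- ensemble$draws
  mu_mat <- vapply(seq_len(nrow(dr)), function(i) {
    tryCatch(
      back_flux_extent(setup,
                       dr[i, c("c0", "c1", "lam")],
                       dr[i, c("d0", "d1", "d2", "k")],
                       constants, times, tol)$mu,
      error = function(e) rep(NA_real_, length(times)))
  }, numeric(length(times)))
  qs <- apply(mu_mat, 1, quantile, probs = c(0.5, 0.025, 0.975),
              na.rm = TRUE)
  data.frame(time = times, mu_med = qs[1, ], mu_lo95 = qs[2, ],
             mu_hi95 = qs[3, ],
             n_valid = apply(mu_mat, 1, function(r) sum(!is.na(r))))
}
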