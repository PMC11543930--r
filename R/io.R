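# Time-series, trajectory and configuration I/O.  Fixed unit system:
# time in days, concentrations in mmol/L, delta-13C in permil VPDB,
# energies in kJ/mol -- encoded in the column-name suffixes and
# validated at parse time.

.TS_COLUMNS <- c("time_d", "butane_mmol_l", "sulfide_mmol_l",
                 "d13c_butane_permil", "replicate")

#' Read an incubation time series
#'
#' Expects a comma-separated file with header columns `time_d`,
#' `butane_mmol_l`, `sulfide_mmol_l`, `d13c_butane_permil`, `replicate`
#' (the unit suffixes double as a unit check).  Rows are sorted by time;
#' concentrations must be non-negative and times non-negative.
#'
#' @param path CSV path.
#' @return Data frame of class `"isotope_timeseries"`, sorted by time.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.TS_COLUMNS, names(df))
  if (length(missing))
    .stopf("time series lacks column(s): %s (units are part of the name)",
           paste(missing, collapse = ", "))
  if (any(df$time_d < 0)) .stopf("negative time in %s", path)
  for (cc in c("butane_mmol_l", "sulfide_mmol_l")) {
    if (any(df[[cc]] < 0, na.rm = TRUE))
      .stopf("negative concentration in column %s", cc)
  }
  df <- df[order(df$time_d, df$replicate), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("isotope_timeseries", "data.frame")
  df
}

#' Write an incubation time series
#'
#' @param data Data frame with the standard time-series columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(data, path) {
  missing <- setdiff(.TS_COLUMNS, names(data))
  if (length(missing))
    .stopf("time series lacks column(s): %s", paste(missing, collapse = ", "))
  out <- as.data.frame(data)[.TS_COLUMNS]
  for (cc in setdiff(.TS_COLUMNS, "replicate"))
    out[[cc]] <- signif(out[[cc]], 9)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a back-flux trajectory
#'
#' Deterministic column order, nine significant digits.  When posterior
#' bands are supplied their columns are merged in.
#'
#' @param trajectory A `"backflux_trajectory"` (see [back_flux_extent()]).
#' @param path Output CSV path.
#' @param bands Optional posterior band table from [posterior_backflux()].
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, bands = NULL) {
  cols <- c("time", "mu", "f_minus", "f_plus", "v", "f_net", "valid")
  out <- as.data.frame(trajectory)[cols]
  if (!is.null(bands)) {
    out$mu_lo95 <- bands$mu_lo95[match(out$time, bands$time)]
    out$mu_hi95 <- bands$mu_hi95[match(out$time, bands$time)]
  }
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, 9)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a posterior ensemble
#'
#' Writes the draws as CSV preceded by a '#'-prefixed diagnostics block
#' (integrated autocorrelation time and split R-hat per parameter,
#' acceptance rates, settings); [read_ensemble()] restores the draws.
#'
#' @param ensemble A `"posterior_ensemble"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "posterior_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  d <- ensemble$diagnostics
  writeLines(c(
    "# posterior ensemble",
    sprintf("# chains=%d steps=%d burn_in=%d draws=%d seed=%s",
            ensemble$chains, ensemble$steps, ensemble$burn_in,
            nrow(ensemble$draws),
            if (is.null(ensemble$seed)) "NA" else ensemble$seed),
    sprintf("# acceptance conc=%.4f delta=%.4f converged=%s",
            ensemble$acceptance[1], ensemble$acceptance[2],
            ensemble$converged),
    sprintf("# diag %s tau=%.6g rhat=%.6g", rownames(d), d[, "tau"],
            d[, "rhat"])
  ), con)
  utils::write.table(signif(as.data.frame(ensemble$draws), 9), con,
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read posterior draws written by [write_ensemble()]
#'
#' @param path Ensemble CSV path.
#' @return Matrix of draws (comment block skipped).
#' @export
read_ensemble <- function(path) {
  as.matrix(read.csv(path, comment.char = "#"))
}

#' Read a run configuration
#'
#' A YAML file holding any of the [experiment_config()],
#' [isotope_constants()] and MCMC settings plus a seed; missing entries
#' fall back to package defaults.  [write_run_config()] round-trips it.
#'
#' @param path YAML path.
#' @return List of class `"run_config"` with elements `experiment`
#'   (an `"experiment_config"`), `constants` (an
#'   `"isotope_constants"`), `inference` (list), `seed`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  exp_args <- raw$experiment
  cfg <- do.call(experiment_config, if (is.null(exp_args)) list()
                 else exp_args)
  const <- do.call(isotope_constants,
                   if (is.null(raw$constants)) list() else raw$constants)
  structure(list(experiment = cfg, constants = const,
                 inference = raw$inference, seed = raw$seed),
            class = "run_config")
}

#' @rdname read_run_config
#' @param config A `"run_config"` (or plain list in the same shape).
#' @export
write_run_config <- function(config, path) {
  payload <- list(
    experiment = unclass(config$experiment),
    constants = unclass(config$constants),
    inference = config$inference,
    seed = config$seed
  )
  yaml::write_yaml(payload, path)
  invisible(path)
}
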