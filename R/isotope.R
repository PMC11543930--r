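# Stable carbon isotope bookkeeping: delta / ratio / fractional-abundance
# conversions on the VPDB scale, Rayleigh fractionation estimation, and
# flux-force diagnostics.

#' Isotope constants for the mass-balance model
#'
#' @param alpha_plus Kinetic fractionation factor of the forward
#'   (oxidative) flux (default 0.9975, i.e. an enrichment factor of
#'   -2.5 permil).
#' @param alpha_minus Fractionation factor of the back flux (default 1;
#'   experimentally inaccessible, and the back-flux estimate is robust to
#'   values down to 0.90).
#' @param n Carbon atoms per alkane molecule (4 for butane).
#' @param r_std 13C/12C ratio of the VPDB standard.
#' @return List of class `"isotope_constants"`.
#' @export
isotope_constants <- function(alpha_plus = 0.9975, alpha_minus = 1,
                              n = 4L, r_std = 0.01123720) {
  if (alpha_plus < 0.99 || alpha_plus > 1)
    .stopf("alpha_plus must lie in [0.99, 1]")
  if (alpha_minus < 0.9 || alpha_minus > 1)
    .stopf("alpha_minus must lie in [0.9, 1]")
  if (n < 2 || n != round(n)) .stopf("n must be an integer >= 2")
  structure(list(alpha_plus = alpha_plus, alpha_minus = alpha_minus,
                 n = as.integer(n), r_std = r_std),
            class = "isotope_constants")
}

#' Labeling setup of an incubation
#'
#' Fixes the initial pools of a closed-system labeling experiment and the
#' two conserved totals derived from them: total carbon
#' `[C]0 = dic0 + n alk0` and total 13C
#' `[13C]0 = atom13_dic0 * dic0 + F0_alk * n * alk0`.
#'
#' @param alk0 Initial alkane, mmol L^-1.
#' @param dic0 Initial dissolved inorganic carbon, mmol L^-1.
#' @param atom13_dic0 Initial 13C atom fraction of the DIC pool
#'   (0.0112 for natural abundance up to 0.98).
#' @param delta0_alk Initial delta-13C of the alkane, permil VPDB.
#' @param constants An `"isotope_constants"` (supplies n and the
#'   standard ratio).
#' @return List of class `"labeling_setup"` with elements `alk0`, `dic0`,
#'   `atom13_dic0`, `delta0_alk`, `c_total`, `c13_total`.
#' @examples
#' labeling_setup()$c13_total  # 17.9001 mmol 13C / L at 98 atom%
#' @export
labeling_setup <- function(alk0 = 6, dic0 = 18, atom13_dic0 = 0.98,
                           delta0_alk = -25,
                           constants = isotope_constants()) {
  .assert_numeric(alk0, "alk0", positive = TRUE)
  .assert_numeric(dic0, "dic0", positive = TRUE)
  if (atom13_dic0 < 0.0112 || atom13_dic0 > 0.98)
    .stopf("atom13_dic0 must lie in [0.0112, 0.98]")
  f0 <- delta_to_frac(delta0_alk, constants$r_std)
  structure(list(
    alk0 = alk0, dic0 = dic0, atom13_dic0 = atom13_dic0,
    delta0_alk = delta0_alk,
    c_total = dic0 + constants$n * alk0,
    c13_total = atom13_dic0 * dic0 + f0 * constants$n * alk0
  ), class = "labeling_setup")
}

#' Convert between delta-13C, isotope ratio and fractional abundance
#'
#' `R = R_std (1 + delta/1000)`, `F = R / (1 + R)`; the conversions
#' round-trip exactly.
#'
#' @param delta delta-13C in permil VPDB (> -1000).
#' @param ratio 13C/12C ratio (0 < R).
#' @param frac 13C atom fraction (0 < F < 1).
#' @param r_std Standard ratio (VPDB).
#' @return The converted quantity, vectorised.
#' @examples
#' delta_to_ratio(0)        # 0.01123720
#' delta_to_ratio(-25)      # 0.01095627
#' frac_to_delta(delta_to_frac(-25))
#' @name isotope-conversions
NULL

#' @rdname isotope-conversions
#' @export
delta_to_ratio <- function(delta, r_std = 0.01123720) {
  if (any(delta <= -1000)) .stopf("delta must exceed -1000 permil")
  r_std * (1 + delta / 1000)
}

#' @rdname isotope-conversions
#' @export
ratio_to_delta <- function(ratio, r_std = 0.01123720) {
  .assert_numeric(ratio, "ratio", positive = TRUE)
  (ratio / r_std - 1) * 1000
}

#' @rdname isotope-conversions
#' @export
ratio_to_frac <- function(ratio) {
  .assert_numeric(ratio, "ratio", positive = TRUE)
  ratio / (1 + ratio)
}

#' @rdname isotope-conversions
#' @export
frac_to_ratio <- function(frac) {
  if (any(frac <= 0) || any(frac >= 1)) .stopf("frac must lie in (0, 1)")
  frac / (1 - frac)
}

#' @rdname isotope-conversions
#' @export
delta_to_frac <- function(delta, r_std = 0.01123720)
  ratio_to_frac(delta_to_ratio(delta, r_std))

#' @rdname isotope-conversions
#' @export
frac_to_delta <- function(frac, r_std = 0.01123720)
  ratio_to_delta(frac_to_ratio(frac), r_std)

#' Rayleigh estimate of the forward fractionation factor
#'
#' Regresses `ln((delta + 1000) / (delta0 + 1000))` of the residual
#' substrate on `ln f`, the fraction of substrate remaining (logarithmic
#' form of the Rayleigh equation).  The slope estimates `alpha_plus - 1`;
#' the enrichment factor is `epsilon = slope * 1000` permil.  Intended
#' for natural-abundance series, where back-flux label transfer is
#' negligible.
#'
#' @param time Time (d), only used to order the series.
#' @param alk Alkane concentrations (the first value is the initial pool).
#' @param delta delta-13C of the residual alkane, permil.
#' @return List with `alpha_plus`, `epsilon` (permil) and the `lm` fit.
#' @examples
#' f <- seq(1, 0.1, length.out = 9)
#' d <- (-25 + 1000) * f^-0.0025 - 1000
#' rayleigh_alpha(seq_along(f), 6 * f, d)$epsilon  # -2.5
#' @export
rayleigh_alpha <- function(time, alk, delta) {
  ord <- order(time)
  alk <- alk[ord]; delta <- delta[ord]
  f <- alk / alk[1]
  use <- which(f > 0 & f < 1)
  if (length(use) < 3)
    .stopf("need at least 3 points with remaining fraction in (0, 1)")
  if (any(f <= 0)) .stopf("remaining fraction must stay positive")
  y <- log((delta[use] + 1000) / (delta[1] + 1000))
  fit <- lm(y ~ log(f[use]))
  slope <- unname(coef(fit)[2])
  list(alpha_plus = 1 + slope, epsilon = slope * 1000, fit = fit)
}

#' Flux-force relation between free energy and reversibility
#'
#' The back-to-forward flux ratio of a net-forward process is
#' `f-/f+ = exp(dG/RT)`; relative to the net rate it is
#' `f-/f_net = 1 / (exp(-dG/RT) - 1)`, which increases monotonically as
#' the thermodynamic drive weakens (dG -> 0 from below).
#'
#' @param dg Free energy of the overall process, kJ mol^-1 (must be
#'   negative: net direction undefined otherwise).
#' @param temperature Kelvin.
#' @return Data frame with `dg`, `ratio_plus` (f-/f+) and `ratio_net`
#'   (f-/f_net).
#' @examples
#' flux_force(-17.1)$ratio_net  # about 1e-3
#' @export
flux_force <- function(dg, temperature = 298) {
  .assert_numeric(dg, "dg")
  if (any(dg >= 0))
    .stopf("dg must be negative: the net direction is undefined at dg >= 0")
  rt <- .rt(temperature)
  data.frame(dg = dg,
             ratio_plus = exp(dg / rt),
             ratio_net = 1 / (exp(-dg / rt) - 1))
}

#' Free energy of the overall sulfate-coupled process along an incubation
#'
#' Evaluates `dG = dG0 + RT ln Q` for
#' `C4H10 + 3.25 SO4^2- -> 4 HCO3- + 3.25 HS- + 0.75 H+ + H2O`
#' at each time point from measured (or simulated) concentrations, with
#' the proton term absorbed into the supplied pH 7 standard value.
#' Activities are taken equal to concentrations (mol L^-1).
#'
#' @param butane,sulfate,sulfide,dic Concentrations in mmol L^-1
#'   (vectors of equal length).
#' @param dg0_overall Standard free energy of the overall process,
#'   kJ mol^-1 (a required configuration constant; the package does not
#'   invent a default).
#' @param temperature Kelvin.
#' @return Numeric vector of free energies (kJ mol^-1); time points with
#'   non-positive concentrations are NA.
#' @export
overall_delta_g <- function(butane, sulfate, sulfide, dic, dg0_overall,
                            temperature = 298) {
  .assert_numeric(dg0_overall, "dg0_overall")
  stopifnot(length(butane) == length(sulfate),
            length(butane) == length(sulfide),
            length(butane) == length(dic))
  rt <- .rt(temperature)
  ok <- butane > 0 & sulfate > 0 & sulfide > 0 & dic > 0
  out <- rep(NA_real_, length(butane))
  # mmol/L -> mol/L activities
  b <- butane[ok] / 1000; s4 <- sulfate[ok] / 1000
  hs <- sulfide[ok] / 1000; hc <- dic[ok] / 1000
  out[ok] <- dg0_overall + rt * (4 * log(hc) + 3.25 * log(hs) -
                                   log(b) - 3.25 * log(s4))
  out
}
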