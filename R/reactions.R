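# The 17-reaction description of the anaerobic butane oxidation (AOB)
# pathway: butane activation by ACR (1-2), butyl-CoM to butyryl-CoA
# conversion (3), beta-oxidation (4-8), oxidative Wood-Ljungdahl (9-14)
# and membrane electron transport to the external carrier X (15-17).
# Standard free energies are at pH 7, 298 K; reactions 3 and 17 depend
# linearly on Ex, the standard redox potential of the XH2/X couple.

# substrate-derived carbon atoms per species; cofactor backbones count 0
.CARBON <- c(
  "C4H10" = 4, "C4H9-S-CoM" = 4, "Butyryl-CoA" = 4, "Crotonyl-CoA" = 4,
  "3-Hydroxybutyryl-CoA" = 4, "Acetoacetyl-CoA" = 4, "Acetyl-CoA" = 2,
  "CH3-H4MPT" = 1, "CH2-H4MPT" = 1, "CH-H4MPT" = 1, "CHO-H4MPT" = 1,
  "CHO-MF" = 1, "CO2" = 1
)

# redox couples solved as a single ln(reduced/oxidized) unknown
.COUPLES <- list(
  NAD  = c(red = "NADH",   ox = "NAD+"),
  F420 = c(red = "F420H2", ox = "F420"),
  Fd   = c(red = "Fd_red", ox = "Fd_ox"),
  MQ   = c(red = "MQH2",   ox = "MQ"),
  X    = c(red = "XH2",    ox = "X")
)

# Parse "2 A + B = C + 3 D" into a signed-coefficient named vector
# (reactants negative, products positive).  H+ is kept; balance checks and
# the quasi-equilibrium system drop it (absorbed into dG0' at pH 7).
.parse_equation <- function(eq) {
  sides <- strsplit(eq, " = ", fixed = TRUE)[[1]]
  if (length(sides) != 2L) .stopf("equation '%s' must contain one ' = '", eq)
  one_side <- function(s, sign) {
    terms <- strsplit(s, " + ", fixed = TRUE)[[1]]
    out <- numeric(0)
    for (term in trimws(terms)) {
      m <- regmatches(term, regexec("^([0-9]+) (.*)$", term))[[1]]
      if (length(m) == 3L) {
        coef <- as.numeric(m[2]); sp <- m[3]
      } else {
        coef <- 1; sp <- term
      }
      out[sp] <- (if (is.na(out[sp])) 0 else out[sp]) + sign * coef
    }
    out
  }
  lhs <- one_side(sides[1], -1)
  rhs <- one_side(sides[2], +1)
  all_sp <- union(names(lhs), names(rhs))
  s <- setNames(numeric(length(all_sp)), all_sp)
  s[names(lhs)] <- s[names(lhs)] + lhs
  s[names(rhs)] <- s[names(rhs)] + rhs
  s[abs(s) > 0]
}

.format_equation <- function(stoich) {
  side <- function(sel) {
    paste(vapply(names(sel), function(sp) {
      cf <- abs(sel[[sp]])
      if (cf == 1) sp else paste(cf, sp)
    }, character(1)), collapse = " + ")
  }
  paste(side(stoich[stoich < 0]), "=", side(stoich[stoich > 0]))
}

#' The shipped 17-reaction AOB table
#'
#' Reads the packaged reaction table (index, enzyme, stoichiometric
#' multiplicity, standard free energy as either a constant or a linear form
#' `a * Ex + b` in kJ mol^-1, and the reaction equation) and parses each
#' equation into signed stoichiometric coefficients.  The table sums, with
#' its multiplicities, to the net pathway
#' `C4H10 + 8 H2O + 13 X -> 4 CO2 + 13 XH2`.
#'
#' @param path Path to a tab-separated reaction table; defaults to the
#'   version shipped with the package.
#' @return A data frame of class `"reaction_table"` with one row per
#'   reaction and a list column `stoich` of named signed coefficients
#'   (reactants negative, products positive).
#' @examples
#' rt <- aob_reactions()
#' rt$equation[1]
#' @export
aob_reactions <- function(path = system.file("extdata", "aob_reactions.tsv",
                                             package = "backflux")) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("index", "enzyme", "multiplicity", "dg0_const", "dg0_a",
            "dg0_b", "equation")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    .stopf("reaction table lacks column(s): %s", paste(missing, collapse = ", "))
  raw$stoich <- lapply(raw$equation, .parse_equation)
  for (i in seq_len(nrow(raw))) {
    s <- raw$stoich[[i]]
    s <- s[names(s) != "H+"]
    cb <- sum(s * .CARBON[names(s)], na.rm = TRUE)
    if (abs(cb) > 1e-9)
      .stopf("reaction %d does not balance carbon (net %g atoms)", raw$index[i], cb)
  }
  class(raw) <- c("reaction_table", "data.frame")
  raw
}

#' Write a reaction table back to TSV
#'
#' Inverse of [aob_reactions()]; the written file re-reads to an identical
#' table (equations are re-serialised from the parsed coefficients).
#'
#' @param reactions A `"reaction_table"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reactions <- function(reactions, path) {
  out <- as.data.frame(reactions)
  out$equation <- vapply(out$stoich, .format_equation, character(1))
  out$stoich <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Standard free energy of one pathway reaction
#'
#' Evaluates the standard transformed Gibbs energy (kJ mol^-1, pH 7, 298 K)
#' of a single reaction.  Most reactions carry a tabulated constant; the
#' butyl-CoM/butyryl-CoA conversion (reaction 3) and the MQH2-to-X electron
#' transfer (reaction 17) depend on the redox potential `Ex` (V) of the
#' external two-electron carrier through the linear forms
#' `-386 Ex - 55.801` and `-193 Ex - 15.440`.
#'
#' @param index Reaction index (1-17 for the shipped table).
#' @param Ex Standard redox potential of the XH2/X couple in volt.
#' @param reactions Reaction table, defaulting to the shipped one.
#' @return Standard free energy change in kJ mol^-1.
#' @examples
#' delta_g0_prime(3, -0.414)   # 104.003
#' delta_g0_prime(17, -0.220)  # 27.020
#' @export
delta_g0_prime <- function(index, Ex, reactions = aob_reactions()) {
  .assert_numeric(Ex, "Ex")
  i <- match(index, reactions$index)
  if (any(is.na(i)))
    .stopf("unknown reaction index: %s",
           paste(index[is.na(i)], collapse = ", "))
  dg <- reactions$dg0_const[i]
  lin <- is.na(dg)
  dg[lin] <- reactions$dg0_a[i][lin] * Ex + reactions$dg0_b[i][lin]
  dg
}
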