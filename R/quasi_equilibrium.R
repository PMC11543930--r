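# Quasi-equilibrium solution of the pathway: every reaction is held at a
# target free energy -- 0 at equilibrium steps, n_H * proton_quantum at
# proton-motive-force (PMF) coupled steps -- and the resulting linear
# system in the log activities of the internal metabolites and the log
# ratios of the redox couples is solved.  One designated dissipation
# reaction is left out of the system; its free energy is recovered
# afterwards as the slack that closes the pathway energy balance.

#' Define how reactions couple to the proton motive force
#'
#' Every reaction is at equilibrium except the PMF-coupled sites, which
#' are pinned at `n_H * proton_quantum`, and one dissipation reaction
#' whose free energy is solved as slack.  Positive `n_H` means protons
#' translocated outward (energy conserved at an exergonic step); negative
#' `n_H` means protons consumed (energy invested to push an endergonic
#' step).  Defaults place investment at the butyl-CoM/butyryl-CoA
#' conversion (3) and the MQH2-to-X electron transfer (17), recovery at
#' F420H2 and ferredoxin oxidation (15, 16), and dissipation at
#' methylene-H4MPT oxidation (11) for the oxidative direction; the
#' reverse direction mirrors the signs and dissipates at acetyl-CoA
#' synthesis (reverse of 9).
#'
#' @param model A `"pathway_model"` (used only for its direction and to
#'   validate indices).
#' @param pmf Named integer vector: reaction index -> n_H.
#' @param dissipation Index of the single dissipation reaction.
#' @return An object of class `"coupling_scheme"`.
#' @examples
#' coupling_scheme(pathway_model())
#' @export
coupling_scheme <- function(model,
                            pmf = .default_pmf(model),
                            dissipation = .default_dissipation(model)) {
  stopifnot(inherits(model, "pathway_model"))
  if (is.null(pmf)) pmf <- setNames(integer(0), character(0))
  if (length(dissipation) != 1L)
    .stopf("exactly one dissipation reaction per scheme (or NA for none)")
  idx <- model$reactions$index
  bad <- setdiff(c(as.integer(names(pmf)),
                   if (!is.na(dissipation)) dissipation), idx)
  if (length(bad))
    .stopf("scheme references unknown reaction index: %s",
           paste(bad, collapse = ", "))
  if (!is.na(dissipation) && as.character(dissipation) %in% names(pmf))
    .stopf("the dissipation reaction cannot also be a pmf site")
  structure(list(pmf = pmf, dissipation = as.integer(dissipation),
                 net_protons = .net_protons(model, pmf)),
            class = "coupling_scheme")
}

.default_pmf <- function(model) {
  if (model$direction == "aob")
    c("3" = -1, "15" = 2, "16" = 2, "17" = -1)
  else
    c("3" = 1, "15" = -2, "16" = -2, "17" = 1)
}

.default_dissipation <- function(model)
  if (model$direction == "aob") 11L else 9L

# net protons conserved per mole of butane: sum of multiplicity * n_H
.net_protons <- function(model, pmf) {
  if (!length(pmf)) return(0L)
  i <- match(as.integer(names(pmf)), model$reactions$index)
  sum(model$reactions$multiplicity[i] * pmf)
}

#' @export
print.coupling_scheme <- function(x, ...) {
  cat("Coupling scheme:\n  pmf sites:",
      if (length(x$pmf)) paste(sprintf("%s (n_H=%+d)", names(x$pmf), x$pmf),
                               collapse = ", ") else "none",
      "\n  dissipation at reaction", x$dissipation,
      "\n  net protons:", x$net_protons, "\n")
  invisible(x)
}

# classify every species of the model as boundary / couple member / solved
.species_roles <- function(model) {
  st <- .model_stoich(model)
  all_sp <- unique(unlist(lapply(st, names)))
  all_sp <- setdiff(all_sp, "H+")
  couple_members <- unlist(lapply(.COUPLES, unname), use.names = FALSE)
  list(
    boundary = intersect(all_sp, names(model$boundary)),
    couples = Filter(function(cp) any(cp %in% all_sp), .COUPLES),
    solved = setdiff(all_sp, c(names(model$boundary), couple_members))
  )
}

#' Solve the quasi-equilibrium concentration system
#'
#' Builds one linear equation per non-dissipation reaction,
#' `sum_i s_ij ln a_i = (dG_target_j - dG0'_j) / RT`, in the log
#' activities of the solved metabolites and the log reduced/oxidized
#' ratios of the internal redox couples, with boundary activities and the
#' XH2/X ratio substituted as constants.  The dissipation reaction's free
#' energy is recovered from the solution, and per-reaction free energies,
#' the catabolic total and a feasibility verdict (all solved activities
#' inside the physiological window and non-positive dissipation) are
#' reported.
#'
#' @param model A `"pathway_model"`.
#' @param scheme A `"coupling_scheme"`; defaults to the direction's
#'   default scheme.
#' @param low,high Physiological activity window (mol L^-1) used for the
#'   feasibility verdict; redox ratios are dimensionless and exempt.
#' @return An object of class `"qe_solution"` with elements
#'   `log_activities`, `activities`, `redox_ratios`, `per_reaction_dg`,
#'   `dissipation_dg`, `catabolic_dg`, `residual_norm`, `feasible` and
#'   `violations`.
#' @examples
#' sol <- qe_solve(pathway_model())
#' sol$feasible
#' @export
qe_solve <- function(model, scheme = coupling_scheme(model),
                     low = 1e-6, high = 1e-2) {
  stopifnot(inherits(model, "pathway_model"),
            inherits(scheme, "coupling_scheme"))
  roles <- .species_roles(model)
  couple_of <- character(0)   # species -> couple name
  couple_sign <- numeric(0)   # +1 reduced, -1 oxidized
  for (cn in names(roles$couples)) {
    cp <- roles$couples[[cn]]
    couple_of[cp[["red"]]] <- cn; couple_sign[cp[["red"]]] <- +1
    couple_of[cp[["ox"]]] <- cn;  couple_sign[cp[["ox"]]] <- -1
  }
  ratio_unknowns <- setdiff(names(roles$couples), "X")
  unknowns <- c(roles$solved,
                paste0("ratio:", ratio_unknowns, recycle0 = TRUE))
  if (!length(unknowns)) .stopf("model has no unknown species to solve")

  st <- .model_stoich(model)
  dg0 <- .model_dg0(model)
  rt <- .rt(model$temperature)
  keep <- if (is.na(scheme$dissipation)) seq_len(nrow(model$reactions))
          else which(model$reactions$index != scheme$dissipation)
  A <- matrix(0, length(keep), length(unknowns),
              dimnames = list(NULL, unknowns))
  b <- numeric(length(keep))
  row_lnq_fixed <- function(s) {
    lnq <- 0
    for (sp in names(s)) {
      if (sp == "H+") next
      if (sp %in% names(couple_of)) {
        # half-weight per member: a balanced couple contributes
        # s_red * ln(ratio) in total
        if (couple_of[[sp]] == "X")
          lnq <- lnq + s[[sp]] * couple_sign[[sp]] * log(model$xh2_x_ratio) / 2
      } else if (sp %in% roles$boundary) {
        lnq <- lnq + s[[sp]] * log(model$boundary[[sp]])
      }
    }
    lnq
  }
  for (r in seq_along(keep)) {
    j <- keep[r]
    s <- st[[j]]
    idx <- model$reactions$index[j]
    target <- if (as.character(idx) %in% names(scheme$pmf))
      scheme$pmf[[as.character(idx)]] * model$proton_quantum else 0
    for (sp in names(s)) {
      if (sp == "H+") next
      if (sp %in% roles$solved) {
        A[r, sp] <- A[r, sp] + s[[sp]]
      } else if (sp %in% names(couple_of) && couple_of[[sp]] != "X") {
        cn <- paste0("ratio:", couple_of[[sp]])
        A[r, cn] <- A[r, cn] + s[[sp]] * couple_sign[[sp]] / 2
      }
    }
    b[r] <- (target - dg0[j]) / rt - row_lnq_fixed(s)
  }

  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    undet <- unknowns[qrA$pivot[(qrA$rank + 1L):ncol(A)]]
    .stopf("quasi-equilibrium system is rank deficient; undetermined: %s",
           paste(sub("^ratio:", "ratio ", undet), collapse = ", "))
  }
  x <- qr.coef(qrA, b)
  resid <- sqrt(sum((A %*% x - b)^2))
  consistent <- resid <= 1e-8 * max(1, sqrt(sum(b^2)))

  log_act <- x[roles$solved]
  ratios <- exp(x[paste0("ratio:", ratio_unknowns, recycle0 = TRUE)])
  names(ratios) <- ratio_unknowns

  # per-reaction dG from the solved activities (dissipation included)
  lookup <- function(sp) {
    if (sp %in% roles$solved) return(log_act[[sp]])
    if (sp %in% names(couple_of)) {
      cn <- couple_of[[sp]]
      lr <- if (cn == "X") log(model$xh2_x_ratio) else log(ratios[[cn]])
      return(couple_sign[[sp]] * lr / 2)  # half-weight per couple member
    }
    log(model$boundary[[sp]])
  }
  per_dg <- vapply(seq_along(st), function(j) {
    s <- st[[j]]
    lnq <- 0
    for (sp in names(s)) if (sp != "H+") lnq <- lnq + s[[sp]] * lookup(sp)
    dg0[j] + rt * lnq
  }, numeric(1))
  names(per_dg) <- model$reactions$index
  dis_dg <- if (is.na(scheme$dissipation)) NA_real_
            else per_dg[[as.character(scheme$dissipation)]]

  act <- exp(log_act)
  viol <- c(
    setNames(rep("below", sum(act < low)), names(act)[act < low]),
    setNames(rep("above", sum(act > high)), names(act)[act > high])
  )
  sol <- structure(list(
    log_activities = log_act, activities = act, redox_ratios = ratios,
    per_reaction_dg = per_dg, dissipation_dg = dis_dg,
    catabolic_dg = tryCatch(catabolic_dg(model),
                            error = function(e) NA_real_),
    residual_norm = resid, consistent = consistent,
    feasible = consistent && length(viol) == 0 &&
      (is.na(dis_dg) || dis_dg <= 0),
    violations = viol, low = low, high = high,
    scheme = scheme, direction = model$direction
  ), class = "qe_solution")
  sol
}

#' @export
print.qe_solution <- function(x, digits = 3, ...) {
  cat(sprintf("Quasi-equilibrium solution (%s)\n", toupper(x$direction)))
  cat("  activities (mol/L):\n")
  print(signif(x$activities, digits))
  cat("  redox ratios (red/ox):", paste(sprintf("%s=%.3g", names(x$redox_ratios),
                                                x$redox_ratios), collapse = ", "), "\n")
  cat(sprintf("  dissipation dG = %.2f kJ/mol, catabolic dG = %.2f kJ/mol\n",
              x$dissipation_dg, x$catabolic_dg))
  cat(sprintf("  residual = %.2e, feasible: %s\n", x$residual_norm, x$feasible))
  if (length(x$violations))
    cat("  out of window:", paste(names(x$violations), x$violations,
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Feasibility report for a quasi-equilibrium solution
#'
#' Re-checks a solved pathway against a physiological activity window:
#' every solved metabolite must fall inside `[low, high]` mol L^-1
#' (dimensionless redox ratios are exempt) and the dissipation free
#' energy must be non-positive.
#'
#' @param solution A `"qe_solution"`.
#' @param low,high Window bounds in mol L^-1 (defaults 1 uM and 10 mM).
#' @return List with `feasible`, per-species `violations` (named vector of
#'   `"below"`/`"above"`) and the bounds used.
#' @export
feasibility <- function(solution, low = 1e-6, high = 1e-2) {
  stopifnot(inherits(solution, "qe_solution"))
  .assert_numeric(low, "low", positive = TRUE)
  .assert_numeric(high, "high", positive = TRUE)
  if (low >= high) .stopf("need low < high")
  act <- solution$activities
  viol <- c(
    setNames(rep("below", sum(act < low)), names(act)[act < low]),
    setNames(rep("above", sum(act > high)), names(act)[act > high])
  )
  list(feasible = solution$consistent && length(viol) == 0 &&
         (is.na(solution$dissipation_dg) || solution$dissipation_dg <= 0),
       violations = viol, low = low, high = high,
       dissipation_dg = solution$dissipation_dg)
}

#' Enumerate proton stoichiometries over the PMF sites
#'
#' The per-site proton counts of a coupling scheme are not observable;
#' only net totals are.  This search enumerates integer `n_H` assignments
#' at each PMF site of `scheme` -- from 0 up to `max_per_site` protons
#' conserved at sites whose standard free energy is exergonic at the
#' model's Ex, and from 0 down to `-max_per_site` protons invested at
#' endergonic sites -- solves each candidate, and returns the feasible
#' schemes sorted by decreasing net protons conserved.  Enumeration order
#' is deterministic, so ties keep a stable order.
#'
#' @param model A `"pathway_model"`.
#' @param scheme Base scheme fixing the PMF sites and dissipation
#'   reaction.
#' @param max_per_site Maximum |n_H| per site (default 4).
#' @param low,high Feasibility window passed to [qe_solve()].
#' @return Data frame with one row per feasible assignment: one `nH_<i>`
#'   column per site, `net_protons`, `dissipation_dg`, `min_activity`,
#'   `max_activity`.  Zero rows when nothing is feasible.
#' @export
net_proton_search <- function(model, scheme = coupling_scheme(model),
                              max_per_site = 4, low = 1e-6, high = 1e-2) {
  stopifnot(inherits(model, "pathway_model"))
  if (max_per_site < 1) .stopf("max_per_site must be >= 1")
  sites <- as.integer(names(scheme$pmf))
  dg0_site <- delta_g0_prime(sites, model$Ex, model$reactions)
  if (model$direction == "raob") dg0_site <- -dg0_site
  ranges <- lapply(dg0_site, function(d)
    if (d > 0) 0L:(-as.integer(max_per_site)) else 0L:as.integer(max_per_site))
  names(ranges) <- as.character(sites)
  grid <- expand.grid(ranges, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pmf <- setNames(as.integer(grid[g, ]), names(ranges))
    cand <- coupling_scheme(model, pmf = pmf,
                            dissipation = scheme$dissipation)
    sol <- qe_solve(model, cand, low = low, high = high)
    if (!sol$feasible) next
    row <- as.list(pmf)
    names(row) <- paste0("nH_", names(ranges))
    row$net_protons <- cand$net_protons
    row$dissipation_dg <- sol$dissipation_dg
    row$min_activity <- min(sol$activities)
    row$max_activity <- max(sol$activities)
    rows[[g]] <- as.data.frame(row)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(matrix(numeric(0), 0,
                             length(sites) + 4,
                             dimnames = list(NULL, c(paste0("nH_", sites),
                                                     "net_protons", "dissipation_dg",
                                                     "min_activity", "max_activity"))))
    return(out)
  }
  out <- do.call(rbind, rows)
  out[order(-out$net_protons), , drop = FALSE]
}
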