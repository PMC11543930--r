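# Shared fixtures, built in code.

RT298 <- 8.314e-3 * 298

# single endergonic conversion A -> B with boundary A
toy_single <- function(dg0 = 10, a_act = 1e-3) {
  tab <- data.frame(index = 1L, enzyme = "toy", multiplicity = 1L,
                    dg0_const = dg0, dg0_a = NA_real_, dg0_b = NA_real_,
                    equation = "A = B", stringsAsFactors = FALSE)
  tab$stoich <- list(c(A = -1, B = 1))
  class(tab) <- c("reaction_table", "data.frame")
  suppressWarnings(pathway_model(reactions = tab, boundary = c(A = a_act)))
}

# two-step chain A -> B -> C; first step exergonic conservation site
toy_chain <- function(dg1 = -45, dg2 = 0, a_act = 1e-4) {
  tab <- data.frame(index = 1:2, enzyme = c("site", "link"),
                    multiplicity = c(1L, 1L),
                    dg0_const = c(dg1, dg2), dg0_a = NA_real_,
                    dg0_b = NA_real_,
                    equation = c("A = B", "B = C"),
                    stringsAsFactors = FALSE)
  tab$stoich <- list(c(A = -1, B = 1), c(B = -1, C = 1))
  class(tab) <- c("reaction_table", "data.frame")
  suppressWarnings(pathway_model(reactions = tab, boundary = c(A = a_act)))
}

default_params <- c(c0 = 0.1, c1 = 6, lam = 0.04,
                    d0 = -25, d1 = 80, d2 = 80, k = 0.08)

noise_free_sim <- function(...) {
  simulate_experiment(experiment_config(noise = NULL, ...))
}
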