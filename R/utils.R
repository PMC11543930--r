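# shared physical constants and small internal helpers

#' Gas constant in kJ mol^-1 K^-1
#' @noRd
.R_GAS <- 8.314e-3

#' RT in kJ mol^-1 at temperature `temp` (K)
#' @noRd
.rt <- function(temp = 298) .R_GAS * temp

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.  `seed = NULL` leaves the RNG alone.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.assert_numeric <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x)) .stopf("'%s' must be numeric", name)
  if (finite && any(!is.finite(x))) .stopf("'%s' must be finite", name)
  if (positive && any(x <= 0)) .stopf("'%s' must be positive", name)
  invisible(x)
}
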