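## internal argument checks; all user-facing errors are thrown without a call

check_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  ok <- if (strict) x > lower else x >= lower
  if (!ok || x > upper)
    stop(sprintf("`%s` must be %s %g", name, if (strict) ">" else ">=", lower),
         call. = FALSE)
  invisible(x)
}

check_numeric_vec <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x))
    stop(sprintf("`%s` must be a non-empty numeric vector without NA", name),
         call. = FALSE)
  bad <- if (strict) x <= lower else x < lower
  if (any(bad))
    stop(sprintf("`%s` must be %s %g (offending indices: %s)", name,
                 if (strict) ">" else ">=", lower,
                 paste(utils::head(which(bad), 5L), collapse = ", ")),
         call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < lower)
    stop(sprintf("`%s` must be an integer >= %d", name, lower), call. = FALSE)
  as.integer(x)
}

## trapezoidal quadrature on a uniform or non-uniform grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

## Derive a per-module sub-seed from one global seed, so adding a module never
## perturbs another module's draws.  Rule: sub-seed = (seed + 10007 * index)
## mod (2^31 - 1), with a fixed module index table.
module_seed_index <- c(
  sde = 1L, fpe = 2L, mechanism = 3L, analyze = 4L, recover = 5L
)

#' Derive a per-module sub-seed from a global seed
#'
#' One global seed is expanded into independent per-module seeds by the fixed
#' rule `(seed + 10007 * index) mod (2^31 - 1)`, with a published index per
#' module (`sde` = 1, `fpe` = 2, `mechanism` = 3, `analyze` = 4,
#' `recover` = 5).  Adding a module therefore never perturbs the draws of
#' another.
#'
#' @param seed Integer global seed.
#' @param module One of `"sde"`, `"fpe"`, `"mechanism"`, `"analyze"`,
#'   `"recover"`.
#' @return An integer sub-seed.
#' @examples
#' derive_seed(1, "sde")
#' @export
derive_seed <- function(seed, module = names(module_seed_index)) {
  module <- match.arg(module)
  check_number(seed, "seed")
  as.integer((abs(seed) + 10007 * module_seed_index[[module]]) %% (2^31 - 1))
}
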