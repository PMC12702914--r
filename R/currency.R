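#' Currency arithmetic on exact cents
#'
#' Reported budget cells are printed to the cent (two decimals of SAR).
#' Binary floating point cannot represent most multiples of 0.01 exactly, so
#' all reported sums are carried out on integer cents: values are converted
#' with `round(x * 100)` and summed as doubles, which is exact for integers
#' below 2^53 (far above any national budget in cents).
#'
#' @param x numeric vector of SAR amounts.
#' @return `as_cents()` returns integer cents (as double); `round_cents()`
#'   returns `x` rounded to the cent; `sum_cents()` returns the exact
#'   cent-sum of all its arguments, in SAR.
#' @examples
#' sum_cents(c(0.1, 0.2)) == 0.3
#' @name currency
NULL

#' @rdname currency
#' @export
as_cents <- function(x) round(x * 100)

#' @rdname currency
#' @export
round_cents <- function(x) round(x * 100) / 100

#' @rdname currency
#' @param ... numeric vectors of SAR amounts, concatenated before summation.
#' @export
sum_cents <- function(...) {
  sum(as_cents(c(...))) / 100
}

#' Canonical cost components and RRMS subgroups
#'
#' The five-component cost decomposition (acquisition, administration --
#' which absorbs premedication at reporting --, monitoring, adverse events,
#' relapse) and the five modelled RRMS subgroups by disease activity and
#' treatment history.
#'
#' @return character vector of component or subgroup identifiers, in
#'   canonical reporting order.
#' @export
bia_components <- function() {
  c("acquisition", "administration", "monitoring", "adverse_events", "relapse")
}

#' @rdname bia_components
#' @export
rrms_subgroups <- function() {
  c("active_naive", "ha_naive", "ha_nonnaive", "agg_naive", "agg_nonnaive")
}

# internal: run expr under a local, restored RNG state
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# internal: validation helper with field naming
check_fraction <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("invalid value for '%s': must be a fraction in [0, 1]", field),
         call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop(sprintf("invalid value for '%s': must be non-negative", field),
         call. = FALSE)
  }
  invisible(x)
}
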