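# shared input checks and small numeric helpers

abort_domain <- function(msg) rlang::abort(msg, class = "erpcea_domain_error")
abort_config <- function(msg) rlang::abort(msg, class = "erpcea_config_error")

check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort_domain(sprintf("`%s` must be finite and non-negative", what))
  }
  invisible(x)
}

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort_config(sprintf("`%s` must lie in [0, 1]", what))
  }
  invisible(x)
}

#' Round to the nearest pound, halves away from zero
#'
#' Display rounding for currency: printed tables report whole pounds with
#' halves rounded up (commercial rounding), while internal arithmetic is
#' kept exact. `round(0.5)` in R rounds to even, hence this helper.
#'
#' @param x Numeric vector of monetary values.
#' @return `x` rounded to the nearest integer, ties away from zero.
#' @examples
#' round_pounds(2479.20)
#' round_pounds(502.5)
#' @export
round_pounds <- function(x) sign(x) * floor(abs(x) + 0.5)

# round to 0.5-day resolution (bed days are recorded in half days)
round_half_day <- function(x) round(x * 2) / 2

# deterministic small integer hash of a string, offset by a master seed;
# keeps per-parameter RNG streams independent of one another
seed_from_id <- function(master_seed, id) {
  codes <- utf8ToInt(id)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147480009
  as.integer((h + as.numeric(master_seed) * 10007) %% 2147480009)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
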