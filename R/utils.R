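#' @keywords internal
"_PACKAGE"

# Shared input checks and small numeric helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x)) stop_domain("`%s` must be numeric", name)
  if (finite && any(!is.finite(x))) stop_domain("`%s` must be finite", name)
  invisible(x)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; printed tables in this field
#' conventionally round half up. `round_half_up(0.45, 1)` is `0.5`.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a stream of child seeds from one master seed, each < 2^31.
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed))
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483647L
}

is_timestamp <- function(x) inherits(x, "POSIXct")

check_increasing_time <- function(ts, name = "timestamp") {
  if (is.unsorted(as.numeric(ts), strictly = TRUE))
    stop_domain("`%s` must be strictly increasing", name)
  invisible(ts)
}
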