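# internal helpers: classed conditions, display rounding, seed streams

stop_pk <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "pooledPK_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_input <- function(msg, ...) stop_pk("pooledPK_input_error", msg, ...)
stop_validation <- function(msg, ...) stop_pk("pooledPK_validation_error", msg, ...)
stop_domain <- function(msg, ...) stop_pk("pooledPK_domain_error", msg, ...)
stop_capacity <- function(msg, ...) stop_pk("pooledPK_capacity_error", msg, ...)
stop_convergence <- function(msg, ...) stop_pk("pooledPK_convergence_error", msg, ...)

#' Round half away from zero
#'
#' Display rounding used for summary tables: halves round away from zero
#' (so 0.25 -> 0.3 at one decimal), unlike [round()]'s round-half-even.
#' Internal pipeline values are never rounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector; `NA` stays `NA`.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # tiny guard against decimal values stored just below a half boundary
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# derived seed streams: one user seed governs cohort, allocation and noise
derive_seed <- function(seed, offset) {
  s <- (as.integer(seed) + 97L * as.integer(offset)) %% 2147483586L
  s + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
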