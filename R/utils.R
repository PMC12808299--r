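# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Display rounding used for millimetre and percentage output. `base::round`
#' rounds half to even; osteometric tables conventionally round 0.05 up.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_positive_finite <- function(x, what = "value") {
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    stopf("%s must be positive and finite; offending entries: %s",
          what, paste(utils::head(which(bad), 10L), collapse = ", "))
  }
  invisible(x)
}

# package-local cache (registry, default bundle)
.osteosex_cache <- new.env(parent = emptyenv())
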