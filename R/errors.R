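# Typed error conditions. Every failure mode has a named class so callers
# (and tests) can distinguish schema problems from numerical degeneracies.

lum_error <- function(message, class, ...) {
  stop(errorCondition(message, ...,
                      class = c(class, "lumbarstretch_error")))
}

#' @keywords internal
lum_stopifnot_finite <- function(x, what) {
  if (!all(is.finite(as.matrix(x)))) {
    lum_error(sprintf("%s contains non-finite values", what),
              class = "lum_nonfinite_error")
  }
  invisible(x)
}
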