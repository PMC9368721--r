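#' Round half away from zero
#'
#' Rounding convention used for reported figures: ties are rounded away from
#' zero at the requested precision (so 0.0075 at 3 decimals gives 0.008),
#' unlike [base::round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_report(2.5, 0)   # 3
#' round_report(-2.5, 0)  # -3
round_report <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## internal: stop with a class so callers can distinguish input errors
cn_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "citenet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

## internal: check a scalar probability
check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    cn_stop(sprintf("field '%s' must be a probability in [0, 1]", field),
            "citenet_config_error")
  }
  invisible(x)
}

## internal: check a non-negative integer count
check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    cn_stop(sprintf("field '%s' must be an integer >= %d", field, min),
            "citenet_config_error")
  }
  invisible(as.integer(x))
}
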