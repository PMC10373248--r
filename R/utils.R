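#' @keywords internal
"_PACKAGE"

#' @useDynLib carplock, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx dgamma optim pgamma plogis qlogis qnorm rgamma
#'   rnorm runif sd setNames median model.matrix quantile rexp
#' @importFrom utils read.csv write.csv modifyList
NULL

# labeled conditions: every user-facing error carries a subclass so callers
# (and tests) can distinguish validation failures from numerical ones
abort <- function(msg, class = "carplock_error", ...) {
  stop(structure(
    class = c(class, "carplock_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Wrap an angle to the interval (-pi, pi]
#'
#' Angles equal to an odd multiple of pi map to +pi, so the returned value is
#' always in the half-open interval used for turning angles.
#'
#' @param a numeric vector of angles in radians.
#' @return numeric vector of the same length with values in (-pi, pi].
#' @examples
#' wrap_angle(3 * pi / 2)   # -pi/2
#' wrap_angle(-pi)          # pi
#' @export
wrap_angle <- function(a) {
  w <- a - 2 * pi * floor((a + pi) / (2 * pi))
  # floor() maps pi to -pi; the convention here is (-pi, pi]
  w[w <= -pi] <- pi
  w
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
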