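#' Wrap angles to (-pi, pi]
#'
#' All headings and relative angles in the package are stored wrapped to the
#' half-open interval (-pi, pi]. A single shared helper prevents drift between
#' modules.
#'
#' @param a numeric vector of angles, radians.
#' @return angles wrapped to (-pi, pi].
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi, -3 * pi / 2))
#' @export
wrap_angle <- function(a) {
  w <- a - 2 * pi * floor((a + pi) / (2 * pi))
  # floor() maps to [-pi, pi); move the lower boundary to +pi
  w[w <= -pi] <- pi
  w
}

stop_unless <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
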