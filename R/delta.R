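#' Delta (per-mil) isotope values with explicit scale and phase
#'
#' A `delta_value` wraps a numeric vector of \eqn{\delta^{18}}O values (in
#' per mil) together with the reference scale on which they are expressed
#' (VSMOW for water measurements, VPDB for carbonates) and the phase the
#' value describes (`"water"` or `"otolith"`). Making the scale explicit
#' prevents the classic blunder of mixing VSMOW water values with VPDB
#' carbonate values in one computation: all arithmetic in this package that
#' combines deltas checks scales first.
#'
#' @param value numeric vector, per mil.
#' @param scale `"VSMOW"` or `"VPDB"`.
#' @param phase `"water"` or `"otolith"`.
#' @return an object of class `delta_value`.
#' @examples
#' d <- delta_value(0.3, "VSMOW", "water")
#' convert_scale(d, "VPDB")
#' @export
delta_value <- function(value, scale = c("VSMOW", "VPDB"),
                        phase = c("water", "otolith")) {
  scale <- match.arg(scale)
  phase <- match.arg(phase)
  stopifnot(is.numeric(value))
  structure(list(value = as.numeric(value), scale = scale, phase = phase),
            class = "delta_value")
}

#' @export
print.delta_value <- function(x, ...) {
  cat(sprintf("<delta_value> %s d18O (%s), n = %d\n",
              x$phase, x$scale, length(x$value)))
  print(x$value, ...)
  invisible(x)
}

#' @export
format.delta_value <- function(x, ...) {
  sprintf("%.3f‰ (%s, %s)", x$value, x$scale, x$phase)
}

is_delta <- function(x) inherits(x, "delta_value")

delta_num <- function(x) if (is_delta(x)) x$value else x

stop_input <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' Convert an isotope ratio to standard delta notation
#'
#' \eqn{\delta = (R_{sample}/R_{standard} - 1) \times 1000} per mil, where
#' R is the heavy-to-light isotope ratio (here \eqn{^{18}}O/\eqn{^{16}}O) of
#' the sample or of the international reference material.
#'
#' @param r_sample,r_standard positive isotope ratios.
#' @return numeric delta value(s), per mil.
#' @examples
#' ratio_to_delta(1.001, 1) # 1 per mil
#' @export
ratio_to_delta <- function(r_sample, r_standard) {
  if (any(!is.finite(r_sample)) || any(!is.finite(r_standard)) ||
      any(r_sample <= 0) || any(r_standard <= 0)) {
    stop_input("isotope ratios must be positive and finite")
  }
  (r_sample / r_standard - 1) * 1000
}

# VSMOW -> VPDB affine conversion for d18O (Friedman & O'Neil-type
# compilation constants): d_VPDB = VSMOW_VPDB_SLOPE * d_VSMOW + VSMOW_VPDB_OFFSET.
VSMOW_VPDB_SLOPE  <- 0.97002
VSMOW_VPDB_OFFSET <- -29.98

#' Convert a delta value between the VSMOW and VPDB scales
#'
#' Applies the standard affine \eqn{\delta^{18}}O scale conversion
#' \eqn{\delta_{VPDB} = 0.97002\,\delta_{VSMOW} - 29.98} (or its exact
#' inverse). The conversion is invertible: a round trip recovers the input
#' to well below 1e-9 per mil.
#'
#' @param d a [delta_value()].
#' @param target `"VSMOW"` or `"VPDB"`.
#' @return a `delta_value` on the target scale, same phase.
#' @export
convert_scale <- function(d, target = c("VSMOW", "VPDB")) {
  target <- match.arg(target)
  if (!is_delta(d)) stop_input("convert_scale() expects a delta_value")
  if (d$scale == target) {
    warning("delta value already on scale ", target, "; returning unchanged")
    return(d)
  }
  v <- if (target == "VPDB") {
    VSMOW_VPDB_SLOPE * d$value + VSMOW_VPDB_OFFSET
  } else {
    (d$value - VSMOW_VPDB_OFFSET) / VSMOW_VPDB_SLOPE
  }
  delta_value(v, target, d$phase)
}
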