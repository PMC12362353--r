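#' Wet-bulb temperature from dry-bulb temperature and relative humidity
#'
#' Closed-form psychrometric approximation of Stull (2011): an empirical fit of
#' wet-bulb temperature as a function of dry-bulb temperature (deg C) and
#' relative humidity (percent, 0-100), valid for standard sea-level pressure.
#' All arctangents are evaluated in radians and the humidity exponents are 1/2
#' and 3/2 (the standard Stull fit). The formula is applied as-is to any finite
#' input with `rh` in \[0, 100\]; inputs outside the fit's stated validity
#' envelope (roughly `rh` in \[5, 99\] and `t` in \[-20, 50\]) are computed, not
#' rejected, and can be counted with [stull_envelope_flags()].
#'
#' @param t Dry-bulb temperature in degrees Celsius (numeric vector).
#' @param rh Relative humidity in percent, in \[0, 100\] (numeric vector,
#'   recycled against `t`).
#' @return Wet-bulb temperature in degrees Celsius, elementwise.
#' @examples
#' stull_wet_bulb(20, 50)   # ~13.70
#' stull_wet_bulb(35, 80)   # ~31.93
#' @references Stull, R. (2011) Wet-bulb temperature from relative humidity
#'   and air temperature. J. Appl. Meteor. Climatol. 50, 2267-2269.
#' @export
stull_wet_bulb <- function(t, rh) {
  if (!is.numeric(t) || !is.numeric(rh)) {
    stop("`t` and `rh` must be numeric", call. = FALSE)
  }
  if (anyNA(t) || anyNA(rh) || any(!is.finite(t)) || any(!is.finite(rh))) {
    stop("non-finite dry-bulb temperature or relative humidity", call. = FALSE)
  }
  if (any(rh < 0) || any(rh > 100)) {
    stop("relative humidity must lie in [0, 100] percent", call. = FALSE)
  }
  t * atan(0.151977 * sqrt(rh + 8.313658)) +
    atan(t + rh) -
    atan(rh - 1.676331) +
    0.00391838 * rh^1.5 * atan(0.023101 * rh) -
    4.686035
}

#' Count readings outside the Stull validity envelope
#'
#' The Stull fit was calibrated for roughly `rh` in \[5, 99\] percent and `t`
#' in \[-20, 50\] deg C. Values outside that envelope are still computed by
#' [stull_wet_bulb()]; this helper reports how many inputs fall outside so a
#' pipeline can log the count.
#'
#' @inheritParams stull_wet_bulb
#' @return Integer count of out-of-envelope readings.
#' @export
stull_envelope_flags <- function(t, rh) {
  n <- max(length(t), length(rh))
  t <- rep_len(t, n)
  rh <- rep_len(rh, n)
  sum(rh < 5 | rh > 99 | t < -20 | t > 50)
}
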