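# Frequency -> RGB -> HSL conversion for a frequency-output colour sensor.
#
# The sensor reports, per colour filter, the mean frequency (kHz) of a square
# wave proportional to light intensity.  White-balance calibration picks a
# per-channel integration time (ms) so that a white reference maps to
# (255, 255, 255); a reading's RGB components are then frequency x time,
# dimensionless on a nominal 8-bit scale.

#' White-balance calibration constants
#'
#' Per-channel integration times (ms) that map channel frequencies (kHz) to
#' RGB components on a nominal 0-255 scale.  Defaults are the device's
#' calibrated constants.
#'
#' @param t_red_ms,t_green_ms,t_blue_ms Per-channel adjustment times in
#'   milliseconds; all strictly positive.
#' @return An object of class `white_balance`.
#' @seealso [calibrate_white_balance()] to derive constants from a white
#'   reference reading.
#' @export
#' @examples
#' wb <- white_balance()
#' frequencies_to_rgb(1.7325, 0.6087, 0.5918, wb)
white_balance <- function(t_red_ms = 81.4097, t_green_ms = 61.5481,
                          t_blue_ms = 54.0988) {
  t <- c(t_red_ms, t_green_ms, t_blue_ms)
  if (!is.numeric(t) || length(t) != 3L || anyNA(t) || any(t <= 0)) {
    stop("white-balance times must be strictly positive numbers", call. = FALSE)
  }
  structure(
    list(t_red_ms = t_red_ms, t_green_ms = t_green_ms, t_blue_ms = t_blue_ms),
    class = "white_balance"
  )
}

#' @export
print.white_balance <- function(x, ...) {
  cat(sprintf("<white_balance> t_red = %.4f ms, t_green = %.4f ms, t_blue = %.4f ms\n",
              x$t_red_ms, x$t_green_ms, x$t_blue_ms))
  invisible(x)
}

#' Calibrate white balance from a white reference reading
#'
#' Chooses per-channel integration times so the white reference maps exactly
#' to (255, 255, 255): `t_C = 255 / f_C` (ms when `f` is in kHz).
#'
#' @param f_red_khz,f_green_khz,f_blue_khz Mean channel frequencies (kHz)
#'   observed on the white reference; all strictly positive.
#' @return A [white_balance()] object.
#' @export
#' @examples
#' wb <- calibrate_white_balance(3.1323, 4.1431, 4.7136)
#' frequencies_to_rgb(3.1323, 4.1431, 4.7136, wb)  # (255, 255, 255)
calibrate_white_balance <- function(f_red_khz, f_green_khz, f_blue_khz) {
  f <- c(f_red_khz, f_green_khz, f_blue_khz)
  if (!is.numeric(f) || length(f) != 3L || anyNA(f) || any(f <= 0)) {
    stop("invalid calibration: white-reference frequencies must be > 0",
         call. = FALSE)
  }
  white_balance(255 / f_red_khz, 255 / f_green_khz, 255 / f_blue_khz)
}

#' Convert channel frequencies to RGB components
#'
#' Applies the white-balance adjustment `C = f_C * t_C` per channel (kHz times
#' ms, dimensionless).  Components land on a nominal 0-255 scale but are not
#' clamped: super-white inputs legally exceed 255 and flow through the HSL
#' formulas unchanged.
#'
#' @param f_red_khz,f_green_khz,f_blue_khz Numeric vectors of channel mean
#'   frequencies (kHz), recycled to a common length; all `>= 0`.
#' @param wb A [white_balance()] object.
#' @return A data frame with columns `R`, `G`, `B`.
#' @export
#' @examples
#' frequencies_to_rgb(2.5312, 2.8258, 2.9179)  # ~ (206, 174, 158)
frequencies_to_rgb <- function(f_red_khz, f_green_khz, f_blue_khz,
                               wb = white_balance()) {
  stopifnot(inherits(wb, "white_balance"))
  f <- data.frame(f_red_khz, f_green_khz, f_blue_khz)
  if (anyNA(f) || any(f < 0)) {
    stop("invalid reading: channel frequencies must be >= 0", call. = FALSE)
  }
  data.frame(
    R = f$f_red_khz * wb$t_red_ms,
    G = f$f_green_khz * wb$t_green_ms,
    B = f$f_blue_khz * wb$t_blue_ms
  )
}

#' Convert RGB components to HSL colour features
#'
#' With `m = max(R, G, B)` and `n = min(R, G, B)`, lightness is
#' `L = (m + n) / 2` on the 0-255 scale, saturation is
#' `S = (m - n) / (m + n)` when `L < 128` and `(m - n) / (510 - (m + n))`
#' otherwise, and hue is the sector formula `60 * (0 + (G - B)/(m - n))`,
#' `60 * (2 + (B - R)/(m - n))` or `60 * (4 + (R - G)/(m - n))` according to
#' which channel attains the maximum (ties resolved in the order R, G, B),
#' wrapped into `[0, 360)`.  Achromatic inputs get `H = 0`, `S = 0` and the
#' `achromatic` flag rather than an error: clear intestinal juice can be
#' near-gray.  Components agreeing to within an absolute spread of `1e-9`
#' (on the 0-255 scale) count as achromatic, so that white-balance
#' round-trips land exactly on gray despite floating-point rounding.
#'
#' @param r,g,b Numeric vectors of RGB components (nominal 0-255 scale, not
#'   clamped), recycled to a common length; all `>= 0`.
#' @return A data frame with columns `H` (degrees, `[0, 360)`), `S`
#'   (`[0, 1]`), `L` (0-255 scale) and `achromatic` (logical).
#' @export
#' @examples
#' rgb_to_hsl(141.04, 37.46, 32.02)  # undiluted blood: H ~ 3, S ~ 0.63
#' rgb_to_hsl(255, 0, 0)             # pure red: H = 0, S = 1
rgb_to_hsl <- function(r, g, b) {
  x <- data.frame(r, g, b)
  if (anyNA(x) || any(x < 0)) {
    stop("RGB components must be >= 0", call. = FALSE)
  }
  m <- pmax(x$r, x$g, x$b)
  n <- pmin(x$r, x$g, x$b)
  d <- m - n
  achrom <- d <= 1e-9
  l <- (m + n) / 2
  s <- ifelse(achrom, 0,
              ifelse(l < 128, d / (m + n), d / (510 - (m + n))))
  h_raw <- ifelse(achrom, 0,
           ifelse(x$r == m, 60 * (0 + (x$g - x$b) / d),
           ifelse(x$g == m, 60 * (2 + (x$b - x$r) / d),
                            60 * (4 + (x$r - x$g) / d))))
  data.frame(H = h_raw %% 360, S = s, L = l, achromatic = achrom)
}

#' Compute H/S colour features from a readings stream
#'
#' Composition of [frequencies_to_rgb()] and [rgb_to_hsl()] over a readings
#' table (see [read_readings_csv()] for the column convention).
#'
#' @param readings Data frame with columns `f_red_khz`, `f_green_khz`,
#'   `f_blue_khz` (and typically `t_s`, `voltage_v`).
#' @param wb A [white_balance()] object.
#' @return `readings` with columns `R`, `G`, `B`, `H`, `S`, `L`,
#'   `achromatic` appended.
#' @export
reading_to_hs <- function(readings, wb = white_balance()) {
  stopifnot(is.data.frame(readings))
  need <- c("f_red_khz", "f_green_khz", "f_blue_khz")
  if (!all(need %in% names(readings))) {
    stop("readings must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rgb <- frequencies_to_rgb(readings$f_red_khz, readings$f_green_khz,
                            readings$f_blue_khz, wb)
  cbind(readings, rgb, rgb_to_hsl(rgb$R, rgb$G, rgb$B))
}

#' Round colour features to reporting precision
#'
#' Hue to the nearest degree and saturation to two decimals — the precision at
#' which the device reports features and at which the decision thresholds are
#' calibrated.  Full precision is kept everywhere else.
#'
#' @param h Hue in degrees.
#' @param s Saturation fraction.
#' @return A list with elements `h` (integer degrees, wrapped so 360 reports
#'   as 0) and `s` (two decimals).
#' @export
hs_reported <- function(h, s) {
  list(h = round(h) %% 360, s = round(s, 2))
}
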