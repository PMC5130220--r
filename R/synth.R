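# Synthetic dilution-series sensor streams.
#
# The bench characterisation measured ten solutions: two simulated intestinal
# juices (colourless; transparent yellow) and a double-dilution series of
# whole blood (hemoglobin 152 mg/ml) from 512-fold down to undiluted.  The
# generator interpolates channel frequencies between those anchors in
# log2(dilution) and adds multiplicative lognormal sensor noise, producing
# readings streams with the same statistical structure as the bench data.

#' Bench characterisation solution table
#'
#' The ten measured solutions: per-channel mean frequencies (kHz) and the
#' hue/saturation values as reported (hue to the nearest degree, saturation
#' to two decimals).  Solutions 1-2 are simulated intestinal juices;
#' solutions 3-10 form the double-dilution series of whole blood.
#'
#' Note on data quality: the reported H/S of solutions 1 and 8 do not follow
#' from the conversion formulas applied to their reported frequencies, and
#' solution 8's frequency triple itself breaks the otherwise monotone
#' hue/saturation trend of the series (its derived hue wraps to ~359 deg).
#' The table reproduces the reported values verbatim; see the methods
#' vignette.
#'
#' @return A data frame with columns `solution`, `label`, `dilution` (`NA`
#'   for the juices), `f_red_khz`, `f_green_khz`, `f_blue_khz`,
#'   `h_reported`, `s_reported`.
#' @export
table1_solutions <- function() {
  data.frame(
    solution = 1:10,
    label = c("intestinal juice 1", "intestinal juice 2",
              paste0(c(512, 256, 128, 64, 32, 16, 4, 1), "x dilution")),
    dilution = c(NA, NA, 512, 256, 128, 64, 32, 16, 4, 1),
    f_red_khz = c(2.6483, 3.0148, 2.8477, 2.7722, 2.6774,
                  2.5312, 2.3521, 2.1432, 1.8243, 1.7325),
    f_green_khz = c(3.2657, 3.9876, 3.7075, 3.5482, 3.3041,
                    2.8258, 1.9657, 1.2072, 0.7237, 0.6087),
    f_blue_khz = c(2.7727, 4.4974, 4.0711, 3.8479, 3.5226,
                   2.9179, 1.8391, 1.4065, 0.6862, 0.5918),
    h_reported = c(46, 60, 41, 35, 28, 20, 14, 9, 4, 3),
    s_reported = c(0.33, 0.10, 0.20, 0.23, 0.27, 0.33, 0.42, 0.51, 0.60, 0.63)
  )
}

#' Dilution-series anchors
#'
#' The blood dilution rows of [table1_solutions()] (dilution 512 down to 1),
#' sorted by dilution, used as interpolation anchors by
#' [frequencies_for_dilution()].
#'
#' @return Data frame with columns `dilution`, `f_red_khz`, `f_green_khz`,
#'   `f_blue_khz`.
#' @export
dilution_anchors <- function() {
  t1 <- table1_solutions()
  a <- t1[!is.na(t1$dilution),
          c("dilution", "f_red_khz", "f_green_khz", "f_blue_khz")]
  a <- a[order(a$dilution), ]
  rownames(a) <- NULL
  a
}

#' Hemoglobin concentration at a dilution ratio
#'
#' Whole blood at 152 mg/ml diluted P-fold has concentration `152 / P`
#' mg/ml; the 64-fold detection boundary corresponds to 2.375 mg/ml.
#'
#' @param p Dilution ratio (fold), `>= 1`.
#' @param c_whole_mg_ml Whole-blood hemoglobin concentration (mg/ml).
#' @return Concentration in mg/ml.
#' @export
#' @examples
#' hemoglobin_concentration(64)  # 2.375
hemoglobin_concentration <- function(p, c_whole_mg_ml = 152) {
  stopifnot(all(p >= 1), c_whole_mg_ml > 0)
  c_whole_mg_ml / p
}

# lognormal factors with unit mean and the given coefficient of variation
.lognormal_factors <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Channel frequencies at a dilution ratio
#'
#' Noise-free values interpolate each channel linearly in `log2(dilution)`
#' between the bracketing anchors (exact at the anchors themselves, since the
#' bench series is a double dilution).  Extrapolation beyond the anchor range
#' `[1, 512]` is refused.  Optional multiplicative lognormal noise with the
#' given coefficient of variation is applied independently per channel;
#' noisy generation requires an explicit integer seed (noise-free paths are
#' seedless and deterministic).
#'
#' @param p Dilution ratios (fold), each in `[1, 512]`; vectorised.
#' @param noise_cv Coefficient of variation of the multiplicative sensor
#'   noise; `0` disables noise.
#' @param seed Integer seed, required when `noise_cv > 0`.  The global RNG
#'   state is left untouched.
#' @param anchors Anchor table as from [dilution_anchors()].
#' @return Data frame with columns `f_red_khz`, `f_green_khz`, `f_blue_khz`,
#'   one row per element of `p`.
#' @export
#' @examples
#' frequencies_for_dilution(64)               # exactly the 64x anchor
#' frequencies_for_dilution(2)                # log2 midpoint of 1x and 4x
frequencies_for_dilution <- function(p, noise_cv = 0, seed = NULL,
                                     anchors = dilution_anchors()) {
  if (any(!is.finite(p)) || any(p < min(anchors$dilution)) ||
      any(p > max(anchors$dilution))) {
    stop("dilution ratio out of the anchor range [",
         min(anchors$dilution), ", ", max(anchors$dilution), "]",
         call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  lx <- log2(anchors$dilution)
  out <- data.frame(
    f_red_khz = approx(lx, anchors$f_red_khz, xout = log2(p))$y,
    f_green_khz = approx(lx, anchors$f_green_khz, xout = log2(p))$y,
    f_blue_khz = approx(lx, anchors$f_blue_khz, xout = log2(p))$y
  )
  if (noise_cv > 0) {
    if (is.null(seed)) {
      stop("noisy generation requires an explicit integer seed",
           call. = FALSE)
    }
    fac <- withr::with_seed(as.integer(seed),
                            .lognormal_factors(3L * nrow(out), noise_cv))
    out <- out * matrix(fac, ncol = 3L)
  }
  out
}

#' Scenario specification for a synthetic capsule run
#'
#' Describes a monitoring run: total duration, the baseline intestinal-juice
#' solution, zero or more bleeding episodes (each a time window during which
#' the film sees blood at a given dilution), sensor noise, and a linearly
#' decaying supply voltage.
#'
#' @param duration_s Total run duration (s), including the dormancy.
#' @param baseline Which juice solution anchors the non-bleeding colour: `1`
#'   (colourless) or `2` (transparent yellow).
#' @param episodes `NULL`, or a data frame with columns `start_s`, `end_s`,
#'   `dilution`; episodes must lie within the duration and must not overlap.
#' @param noise_cv Multiplicative sensor-noise coefficient of variation.
#' @param seed Integer seed; required when `noise_cv > 0`.
#' @param v_start_v Supply voltage at t = 0 (V).
#' @param v_decay_v_per_h Linear voltage decay rate (V/h).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(duration_s, baseline = 2, episodes = NULL,
                          noise_cv = 0.02, seed = NULL,
                          v_start_v = 3.0, v_decay_v_per_h = 0) {
  stopifnot(duration_s > 0, baseline %in% c(1, 2), noise_cv >= 0,
            v_start_v > 0, v_decay_v_per_h >= 0)
  if (!is.null(episodes)) {
    stopifnot(is.data.frame(episodes),
              all(c("start_s", "end_s", "dilution") %in% names(episodes)))
    if (any(episodes$start_s >= episodes$end_s) ||
        any(episodes$start_s < 0) || any(episodes$end_s > duration_s)) {
      stop("scenario error: episodes must lie within [0, duration_s]",
           call. = FALSE)
    }
    ep <- episodes[order(episodes$start_s), ]
    if (nrow(ep) > 1L &&
        any(ep$start_s[-1L] < ep$end_s[-nrow(ep)])) {
      stop("scenario error: overlapping bleed episodes", call. = FALSE)
    }
  }
  if (noise_cv > 0 && is.null(seed)) {
    stop("scenario error: noisy generation requires an integer seed",
         call. = FALSE)
  }
  structure(list(duration_s = duration_s, baseline = baseline,
                 episodes = episodes, noise_cv = noise_cv,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 v_start_v = v_start_v, v_decay_v_per_h = v_decay_v_per_h),
            class = "scenario_spec")
}

#' Generate a synthetic readings stream
#'
#' Emits one reading per duty-cycle period starting when the dormancy
#' elapses.  During a bleed episode the channel frequencies come from
#' [frequencies_for_dilution()] at the episode's dilution; otherwise from the
#' baseline juice anchor.  Multiplicative lognormal noise (if any) is applied
#' to every reading, and the supply voltage decays linearly from its start
#' value.
#'
#' @param spec A [scenario_spec()].
#' @param cfg A [capsule_config()] supplying dormancy and duty-cycle timing.
#' @return A list with `readings` (standard readings data frame, columns
#'   `t_s`, `f_red_khz`, `f_green_khz`, `f_blue_khz`, `voltage_v`) and
#'   `truth` (ground truth per reading: `t_s`, `true_dilution` (`NA` outside
#'   episodes), `true_bleeding`).
#' @export
generate_stream <- function(spec, cfg = capsule_config()) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(cfg, "capsule_config"))
  period <- cfg$sleep_s + cfg$sample_s
  if (spec$duration_s < cfg$dormancy_s) {
    stop("scenario error: duration ends before the dormancy elapses",
         call. = FALSE)
  }
  times <- seq(cfg$dormancy_s, spec$duration_s, by = period)

  t1 <- table1_solutions()
  base <- t1[t1$solution == spec$baseline, ]
  dil <- rep(NA_real_, length(times))
  if (!is.null(spec$episodes)) {
    for (k in seq_len(nrow(spec$episodes))) {
      inside <- times >= spec$episodes$start_s[k] &
        times <= spec$episodes$end_s[k]
      dil[inside] <- spec$episodes$dilution[k]
    }
  }

  f <- data.frame(
    f_red_khz = rep(base$f_red_khz, length(times)),
    f_green_khz = rep(base$f_green_khz, length(times)),
    f_blue_khz = rep(base$f_blue_khz, length(times))
  )
  if (any(!is.na(dil))) {
    f[!is.na(dil), ] <- frequencies_for_dilution(dil[!is.na(dil)])
  }
  if (spec$noise_cv > 0) {
    fac <- withr::with_seed(spec$seed,
                            .lognormal_factors(3L * length(times),
                                               spec$noise_cv))
    f <- f * matrix(fac, ncol = 3L)
  }

  readings <- data.frame(
    t_s = times,
    f_red_khz = f$f_red_khz,
    f_green_khz = f$f_green_khz,
    f_blue_khz = f$f_blue_khz,
    voltage_v = spec$v_start_v - spec$v_decay_v_per_h * times / 3600
  )
  truth <- data.frame(t_s = times, true_dilution = dil,
                      true_bleeding = !is.na(dil))
  list(readings = readings, truth = truth)
}
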