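# Duty-cycled capsule state machine, alarm telemetry, and power budget.
#
# After ingestion the capsule sleeps through an initial dormancy (the enteric
# coating has not yet dissolved), then alternates sleep and short sampling
# windows.  Each processed sample is classified; bleeding emits a severity
# alarm immediately, and a low supply voltage with no bleeding emits a
# (latched) low-battery alarm.

#' Capsule timing, voltage and current configuration
#'
#' Defaults are the device's published operating point: two-hour dormancy,
#' 5 s sleep / 0.5 s sampling duty cycle, a 2.4 V capsule cut-off (the
#' detection module's own threshold is 2.7 V and the transmitter's 1.9 V —
#' both carried for documentation; gating uses only the capsule threshold),
#' 3.0 V regulated supply, and active currents of 2 mA (sensor), 5 mA (LED
#' lighting) and 0.6 mA (microcontroller) with ~0 sleep current.
#'
#' @param dormancy_s Initial dormancy before any sampling (s).
#' @param sleep_s,sample_s Sleep and sampling durations per duty cycle (s);
#'   the cycle period is their sum (5.5 s by default).
#' @param v_capsule Capsule low-voltage cut-off (V).
#' @param v_detect,v_transmit Detection / transmission module thresholds (V),
#'   informational.
#' @param supply_v Regulated supply voltage (V).
#' @param i_sensor_ma,i_led_ma,i_mcu_ma,i_sleep_ma Currents (mA) of the
#'   colour sensor, lighting circuit, microcontroller, and sleep state.
#' @param low_battery_latched Emit the low-battery alarm at most once per run
#'   (default) or on every qualifying sample.
#' @return An object of class `capsule_config`.
#' @export
capsule_config <- function(dormancy_s = 7200, sleep_s = 5, sample_s = 0.5,
                           v_capsule = 2.4, v_detect = 2.7, v_transmit = 1.9,
                           supply_v = 3.0,
                           i_sensor_ma = 2, i_led_ma = 5, i_mcu_ma = 0.6,
                           i_sleep_ma = 0, low_battery_latched = TRUE) {
  if (any(c(sleep_s, sample_s) <= 0) || dormancy_s < 0) {
    stop("durations must be positive (dormancy may be zero)", call. = FALSE)
  }
  if (any(c(i_sensor_ma, i_led_ma, i_mcu_ma, i_sleep_ma) < 0)) {
    stop("currents must be >= 0", call. = FALSE)
  }
  structure(list(dormancy_s = dormancy_s, sleep_s = sleep_s,
                 sample_s = sample_s, v_capsule = v_capsule,
                 v_detect = v_detect, v_transmit = v_transmit,
                 supply_v = supply_v, i_sensor_ma = i_sensor_ma,
                 i_led_ma = i_led_ma, i_mcu_ma = i_mcu_ma,
                 i_sleep_ma = i_sleep_ma,
                 low_battery_latched = isTRUE(low_battery_latched)),
            class = "capsule_config")
}

.alarm_kinds <- c(BLEED_TRACE = 0xA1, BLEED_SMALL = 0xA2, BLEED_LARGE = 0xA3,
                  LOW_BATTERY = 0xF0)
.alarm_leds <- c(BLEED_TRACE = 1L, BLEED_SMALL = 2L, BLEED_LARGE = 3L,
                 LOW_BATTERY = 0L)

#' Encode / decode capsule alarm telemetry
#'
#' Each capsule-to-receiver event is a one-byte code.  Decoding renders the
#' receiver state: any alarm sounds the buzzer; trace, small and large
#' bleeding light one, two and three LEDs; low battery lights none.
#'
#' @param kind One of `"BLEED_TRACE"`, `"BLEED_SMALL"`, `"BLEED_LARGE"`,
#'   `"LOW_BATTERY"`.
#' @return `encode_alarm()`: an integer byte code.  `decode_alarm()`: a list
#'   with `kind`, `buzzer` (logical) and `leds` (0-3).
#' @export
#' @examples
#' decode_alarm(encode_alarm("BLEED_TRACE"))  # buzzer on, one LED
#' decode_alarm(encode_alarm("LOW_BATTERY"))  # buzzer only
encode_alarm <- function(kind) {
  kind <- match.arg(kind, names(.alarm_kinds))
  as.integer(.alarm_kinds[[kind]])
}

#' @rdname encode_alarm
#' @param code Integer byte code produced by `encode_alarm()`.
#' @export
decode_alarm <- function(code) {
  idx <- match(code, .alarm_kinds)
  if (is.na(idx)) stop("protocol error: unknown alarm code ", code,
                       call. = FALSE)
  kind <- names(.alarm_kinds)[idx]
  list(kind = kind, buzzer = TRUE, leds = .alarm_leds[[kind]])
}

.severity_to_kind <- c(trace = "BLEED_TRACE", small = "BLEED_SMALL",
                       large = "BLEED_LARGE")

#' Run the capsule state machine over a readings stream
#'
#' Simulates the capsule work flow: no sample is processed before the
#' dormancy elapses; thereafter at most one sample per duty-cycle period
#' (`sleep_s + sample_s`).  Each processed reading is converted to H/S
#' features and classified at reporting precision ([classify_features()]).
#' A bleeding sample emits one `BLEED_*` alarm immediately (bleeding takes
#' priority over low voltage, whose value is logged); a non-bleeding sample
#' with supply voltage below `v_capsule` emits a `LOW_BATTERY` alarm
#' (latched to at most one per run by default); otherwise nothing is emitted.
#'
#' @param readings Data frame sorted by `t_s` with the standard reading
#'   columns (see [read_readings_csv()]).
#' @param cfg A [capsule_config()].
#' @param wb A [white_balance()].
#' @param area A [target_area()].
#' @param bands A [severity_bands()].
#' @return A list with `events` (data frame `t_s`, `kind`, `payload_hex`,
#'   `buzzer`, `leds`, `h`, `s`, `voltage_v`) and `samples` (per processed
#'   sample: `t_s`, `h`, `s`, `bleeding`, `severity`, `voltage_v`).
#' @export
run_capsule <- function(readings, cfg = capsule_config(),
                        wb = white_balance(), area = target_area(),
                        bands = severity_bands()) {
  stopifnot(is.data.frame(readings), inherits(cfg, "capsule_config"))
  empty_events <- data.frame(t_s = numeric(0), kind = character(0),
                             payload_hex = character(0), buzzer = logical(0),
                             leds = integer(0), h = numeric(0), s = numeric(0),
                             voltage_v = numeric(0))
  empty_samples <- data.frame(t_s = numeric(0), h = numeric(0), s = numeric(0),
                              bleeding = logical(0),
                              severity = factor(character(0),
                                                levels = .severity_levels,
                                                ordered = TRUE),
                              voltage_v = numeric(0))
  if (nrow(readings) == 0L) {
    return(list(events = empty_events, samples = empty_samples))
  }
  if (is.unsorted(readings$t_s)) {
    stop("input error: readings must be sorted by t_s", call. = FALSE)
  }

  period <- cfg$sleep_s + cfg$sample_s
  next_sample <- cfg$dormancy_s
  low_done <- FALSE
  hs <- reading_to_hs(readings, wb)
  events <- list()
  samples <- list()

  for (i in seq_len(nrow(hs))) {
    t <- hs$t_s[i]
    if (t < next_sample) next
    cls <- classify_features(hs$H[i], hs$S[i], area, bands)
    v <- hs$voltage_v[i]
    samples[[length(samples) + 1L]] <-
      data.frame(t_s = t, h = cls$h, s = cls$s, bleeding = cls$bleeding,
                 severity = cls$severity, voltage_v = v)
    kind <- NULL
    if (cls$bleeding) {
      kind <- .severity_to_kind[[as.character(cls$severity)]]
    } else if (v < cfg$v_capsule && !(cfg$low_battery_latched && low_done)) {
      kind <- "LOW_BATTERY"
      low_done <- TRUE
    }
    if (!is.null(kind)) {
      rx <- decode_alarm(encode_alarm(kind))
      events[[length(events) + 1L]] <-
        data.frame(t_s = t, kind = kind,
                   payload_hex = sprintf("%02x", encode_alarm(kind)),
                   buzzer = rx$buzzer, leds = rx$leds,
                   h = cls$h, s = cls$s, voltage_v = v)
    }
    # advance to the first cycle boundary strictly after this sample
    next_sample <- cfg$dormancy_s +
      (floor((t - cfg$dormancy_s) / period) + 1) * period
  }

  list(
    events = if (length(events)) do.call(rbind, events) else empty_events,
    samples = if (length(samples)) do.call(rbind, samples) else empty_samples
  )
}

#' Capsule current and power budget
#'
#' `active_current()` is the sum of sensor, lighting and microcontroller
#' currents while sampling (7.6 mA at the defaults).  `average_current()`
#' weights active and sleep currents by the duty cycle,
#' `(I_active * sample_s + I_sleep * sleep_s) / (sample_s + sleep_s)`
#' (~0.691 mA at the defaults), and `average_power()` multiplies by the
#' supply voltage (~2.07 mW).  `battery_life()` divides the battery capacity
#' by the average current.
#'
#' @param cfg A [capsule_config()].
#' @return Currents in mA, power in mW, battery life in hours.
#' @export
#' @examples
#' active_current(capsule_config())    # 7.6
#' average_current(capsule_config())   # 0.6909...
#' average_power(capsule_config())     # 2.0727...
#' battery_life(capsule_config(), 40)  # 57.89...
active_current <- function(cfg = capsule_config()) {
  stopifnot(inherits(cfg, "capsule_config"))
  cfg$i_sensor_ma + cfg$i_led_ma + cfg$i_mcu_ma
}

#' @rdname active_current
#' @export
average_current <- function(cfg = capsule_config()) {
  stopifnot(inherits(cfg, "capsule_config"))
  (active_current(cfg) * cfg$sample_s + cfg$i_sleep_ma * cfg$sleep_s) /
    (cfg$sample_s + cfg$sleep_s)
}

#' @rdname active_current
#' @export
average_power <- function(cfg = capsule_config()) {
  cfg$supply_v * average_current(cfg)
}

#' @rdname active_current
#' @param capacity_mah Battery capacity in mAh (the device uses two silver
#'   oxide cells of 40 mAh nominal capacity).
#' @export
battery_life <- function(cfg = capsule_config(), capacity_mah = 40) {
  stopifnot(capacity_mah >= 0)
  avg <- average_current(cfg)
  if (capacity_mah == 0) return(0)
  capacity_mah / avg
}
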