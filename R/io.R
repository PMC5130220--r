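# Format plumbing: readings CSV, event-log CSV, flat key=value config,
# PPM/PGM rasters and PNG.

.readings_header <- c("t_s", "f_red_khz", "f_green_khz", "f_blue_khz",
                      "voltage_v")

#' Read and write readings CSV files
#'
#' The stream format is a comma-separated file with header
#' `t_s,f_red_khz,f_green_khz,f_blue_khz,voltage_v`, one row per sample,
#' `.` decimal separator and no thousands separators.  The writer emits the
#' identical dialect at full precision, so read/write round-trips are
#' lossless.
#'
#' @param path File path.
#' @return `read_readings_csv()`: a data frame with the five standard
#'   columns.
#' @export
read_readings_csv <- function(path) {
  if (!file.exists(path)) stop("input error: no such file: ", path,
                               call. = FALSE)
  x <- read.csv(path, colClasses = "numeric")
  if (!identical(names(x), .readings_header)) {
    stop("format error: expected header ",
         paste(.readings_header, collapse = ","), call. = FALSE)
  }
  if (nrow(x) > 0L && is.unsorted(x$t_s)) {
    stop("input error: readings must be sorted by t_s", call. = FALSE)
  }
  x
}

#' @rdname read_readings_csv
#' @param readings Data frame with the five standard columns.
#' @export
write_readings_csv <- function(readings, path) {
  stopifnot(is.data.frame(readings),
            all(.readings_header %in% names(readings)))
  out <- readings[, .readings_header]
  write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a capsule event log CSV
#'
#' Columns `t_s,kind,payload_hex,buzzer,leds` as produced by
#' [run_capsule()].
#'
#' @param events Event data frame from [run_capsule()].
#' @param path File path.
#' @export
write_event_log <- function(events, path) {
  cols <- c("t_s", "kind", "payload_hex", "buzzer", "leds")
  stopifnot(is.data.frame(events), all(cols %in% names(events)))
  write.csv(events[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flat key-value run configuration
#'
#' `default_config()` returns the full default configuration: white-balance
#' times, decision-region bounds, severity cuts, and capsule timing and
#' electrical parameters — all at the device's published values.
#' `read_config()` parses an INI-style flat `key = value` file (`#`
#' comments, blank lines ignored) and overlays it on the defaults; unknown
#' keys are a configuration error.  Every override is reported via a
#' message to keep provenance visible.
#'
#' @return A named list of configuration values.  `severity.cuts` is a
#'   numeric vector of two hues (written in files as comma-separated, e.g.
#'   `severity.cuts = 8,15`).
#' @export
default_config <- function() {
  list(
    `wb.t_red_ms` = 81.4097,
    `wb.t_green_ms` = 61.5481,
    `wb.t_blue_ms` = 54.0988,
    `region.h_low` = 3,
    `region.h_high` = 25,
    `region.s_low` = 0.3,
    `region.s_high` = 0.8,
    `region.wraparound` = FALSE,
    `severity.cuts` = c(8, 15),
    `capsule.dormancy_s` = 7200,
    `capsule.sleep_s` = 5,
    `capsule.sample_s` = 0.5,
    `capsule.v_capsule` = 2.4,
    `capsule.v_detect` = 2.7,
    `capsule.v_transmit` = 1.9,
    `capsule.supply_v` = 3.0,
    `capsule.i_sensor_ma` = 2,
    `capsule.i_led_ma` = 5,
    `capsule.i_mcu_ma` = 0.6,
    `capsule.i_sleep_ma` = 0,
    `capsule.capacity_mah` = 40
  )
}

#' @rdname default_config
#' @param path Path to a flat `key = value` config file, or `NULL` for pure
#'   defaults.
#' @param quiet Suppress override provenance messages.
#' @export
read_config <- function(path = NULL, quiet = FALSE) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config error: no such file: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("config error: expected 'key = value', got: ", ln, call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(cfg)) {
      stop("config error: unknown key: ", key, call. = FALSE)
    }
    parsed <- if (key == "region.wraparound") {
      toupper(val) %in% c("TRUE", "1", "YES")
    } else {
      v <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      if (anyNA(v)) stop("config error: non-numeric value for ", key,
                         call. = FALSE)
      v
    }
    if (!quiet) message("config override: ", key, " = ", val)
    cfg[[key]] <- parsed
  }
  cfg
}

# materialise domain objects from a flat config list
config_wb <- function(cfg) {
  white_balance(cfg$`wb.t_red_ms`, cfg$`wb.t_green_ms`, cfg$`wb.t_blue_ms`)
}
config_area <- function(cfg) {
  target_area(cfg$`region.h_low`, cfg$`region.h_high`,
              cfg$`region.s_low`, cfg$`region.s_high`,
              wraparound = cfg$`region.wraparound`)
}
config_bands <- function(cfg) severity_bands(cfg$`severity.cuts`)
config_capsule <- function(cfg) {
  capsule_config(dormancy_s = cfg$`capsule.dormancy_s`,
                 sleep_s = cfg$`capsule.sleep_s`,
                 sample_s = cfg$`capsule.sample_s`,
                 v_capsule = cfg$`capsule.v_capsule`,
                 v_detect = cfg$`capsule.v_detect`,
                 v_transmit = cfg$`capsule.v_transmit`,
                 supply_v = cfg$`capsule.supply_v`,
                 i_sensor_ma = cfg$`capsule.i_sensor_ma`,
                 i_led_ma = cfg$`capsule.i_led_ma`,
                 i_mcu_ma = cfg$`capsule.i_mcu_ma`,
                 i_sleep_ma = cfg$`capsule.i_sleep_ma`)
}

#' Read an RGB raster (PPM or PNG)
#'
#' PPM (P3 ASCII and P6 binary, maxval <= 255) is parsed directly; PNG goes
#' through the png package.  Either way the result is on the 0-255 scale.
#'
#' @param path Path to a `.ppm` or `.png` file.
#' @return Numeric array `h x w x 3` with values on 0-255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
    if (dim(img)[3] < 3L) img <- array(img[, , 1], dim = c(dim(img)[1:2], 3L))
    return(img[, , 1:3, drop = FALSE] * 255)
  }
  if (ext == "ppm") return(read_ppm(path))
  stop("format error: unsupported image type: ", path, call. = FALSE)
}

#' @rdname read_image
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header tokens: magic, width, height, maxval (comments allowed between)
  tokens <- character(0)
  while (length(tokens) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("format error: truncated PPM header",
                               call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
    } else if (grepl("[[:space:]]", ch)) {
      # skip
    } else {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || grepl("[[:space:]]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (!magic %in% c("P3", "P6") || anyNA(c(w, h, maxval)) || maxval > 255) {
    stop("format error: unsupported PPM (need P3/P6, maxval <= 255)",
         call. = FALSE)
  }
  n <- 3L * w * h
  vals <- if (magic == "P6") {
    as.integer(readBin(con, "raw", n))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop("format error: truncated PPM pixel data",
                             call. = FALSE)
  # PPM stores row-major RGB interleaved
  px <- array(vals, dim = c(3L, w, h))
  aperm(px, c(3L, 2L, 1L)) * (255 / maxval)
}

#' Write a binary mask as ASCII PGM
#'
#' Mask values of 1 are written as 255 and 0 as 0, in P2 (ASCII) format.
#'
#' @param mask Integer/logical matrix.
#' @param path Output path.
#' @export
write_pgm <- function(mask, path) {
  stopifnot(is.matrix(mask))
  vals <- ifelse(as.integer(t(mask)) > 0L, 255L, 0L)
  writeLines(c("P2", paste(ncol(mask), nrow(mask)), "255",
               paste(vals, collapse = " ")), path)
  invisible(path)
}
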