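# Independent textbook HSL oracle (scalar, chroma/mod-6 formulation) used to
# cross-check the sensor-path conversion.  Hue ties resolve R, G, B — the
# same listing order as the sector formulas.
oracle_hsl8 <- function(r, g, b) {
  R <- r / 255; G <- g / 255; B <- b / 255
  mx <- max(R, G, B); mn <- min(R, G, B)
  C <- mx - mn
  L <- (mx + mn) / 2
  S <- if (C == 0) 0 else if (L <= 0.5) C / (2 * L) else C / (2 - 2 * L)
  H <- if (C == 0) {
    0
  } else if (mx == R) {
    60 * (((G - B) / C) %% 6)
  } else if (mx == G) {
    60 * ((B - R) / C + 2)
  } else {
    60 * ((R - G) / C + 4)
  }
  list(h = H %% 360, s = S)
}

# bench solution table and white balance shared across tests
t1 <- bleedcap::table1_solutions()
wb_default <- bleedcap::white_balance()

# readings data frame from solution rows, one per duty cycle after dormancy
solution_stream <- function(rows, t0 = 7200, period = 5.5, voltage = 3.0) {
  data.frame(
    t_s = t0 + (seq_along(rows) - 1) * period,
    f_red_khz = t1$f_red_khz[rows],
    f_green_khz = t1$f_green_khz[rows],
    f_blue_khz = t1$f_blue_khz[rows],
    voltage_v = rep_len(voltage, length(rows))
  )
}
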