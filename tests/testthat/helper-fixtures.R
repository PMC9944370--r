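# Small fixture builders shared across test files.

half_hours <- function(n, start = "2013-01-01 00:00:00") {
  as.POSIXct(start, tz = "UTC") + 1800 * (seq_len(n) - 1L)
}

# a bland meteorological series: no rain, dry leaf sensor, mild diel cycle
make_meteo <- function(n = 96, t_air = NULL, rh = NULL, rain = 0,
                       wetness_resistance = 10000,
                       start = "2013-01-01 00:00:00") {
  h <- ((seq_len(n) - 1L) %% 48L) / 2
  data.frame(
    timestamp = half_hours(n, start),
    t_air = t_air %||% (18 + 5 * cos(2 * pi * (h - 14) / 24)),
    rh = rh %||% rep(60, n),
    rain = rep_len(rain, n),
    wetness_resistance = rep_len(wetness_resistance, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# an exact sigmoid point set for curve-fit tests
sigmoid_points <- function(a, b, psi = seq(-0.5, 2 * b - 0.5, length.out = 25)) {
  data.frame(psi = psi, percent = 100 - 100 / (1 + exp(a * (psi - b))))
}
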