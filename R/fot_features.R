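#' Resistance line over 4-16 Hz
#'
#' Ordinary least-squares fit of resistance against frequency over the
#' 4-16 Hz band (boundaries inclusive), yielding the intercept resistance
#' `R0`, the slope `S` (cmH2O.s/L per Hz, typically negative with peripheral
#' involvement) and the mean resistance `Rm` over the same points.
#'
#' @param spectrum an [impedance_spectrum()] with at least two points in
#'   4-16 Hz.
#' @return Named list with `R0`, `S`, `Rm`.
#' @export
resistance_line <- function(spectrum) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  in_band <- spectrum$frequency_hz >= 4 & spectrum$frequency_hz <= 16
  if (sum(in_band) < 2L)
    stop_oscml("resistance_line needs at least 2 points in 4-16 Hz (got ",
               sum(in_band), ")")
  f <- spectrum$frequency_hz[in_band]
  r <- spectrum$resistance[in_band]
  fit <- lm.fit(cbind(1, f), r)
  list(R0 = unname(fit$coefficients[1]),
       S = unname(fit$coefficients[2]),
       Rm = mean(r))
}

#' Point resistances at 4 and 20 Hz
#'
#' Exact grid lookups of the resistance at 4 Hz (`R4`, whole-airway
#' resistance) and 20 Hz (`R20`, central-airway resistance), and their
#' difference `R4_R20`, an index of small-airway obstruction and ventilation
#' heterogeneity.
#'
#' @param spectrum an [impedance_spectrum()] whose grid contains 4 and 20 Hz.
#' @return Named list with `R4`, `R20`, `R4_R20`.
#' @export
point_resistances <- function(spectrum) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  r_at <- function(f0) {
    i <- which(abs(spectrum$frequency_hz - f0) < 1e-9)
    if (length(i) != 1L)
      stop_oscml("spectrum grid is missing the ", f0, " Hz point")
    spectrum$resistance[i]
  }
  R4 <- r_at(4); R20 <- r_at(20)
  list(R4 = R4, R20 = R20, R4_R20 = R4 - R20)
}

# Linearly interpolated zero crossing of the reactance curve. Falls back to
# linear extrapolation from the last two grid points when reactance stays
# negative through the top of the band, capped at `cap` Hz. Reactance
# non-negative at the first point is reported as the first frequency.
reactance_crossing <- function(freq, x, cap = 64) {
  if (x[1] >= 0) return(freq[1])
  idx <- which(x[-1] >= 0 & x[-length(x)] < 0)
  if (length(idx) > 0) {
    i <- idx[1]
    f1 <- freq[i]; f2 <- freq[i + 1]; x1 <- x[i]; x2 <- x[i + 1]
    if (x2 == x1) return(f2)
    return(f1 - x1 * (f2 - f1) / (x2 - x1))
  }
  n <- length(freq)
  slope <- (x[n] - x[n - 1]) / (freq[n] - freq[n - 1])
  if (slope <= 0) return(cap)
  min(cap, freq[n] - x[n] / slope)
}

#' Reactance-derived indexes
#'
#' Computes from the reactance curve: the mean reactance `Xm` over the
#' 4-32 Hz band; the resonant frequency `Fr` (zero crossing of reactance,
#' linearly interpolated between the bracketing grid points, linearly
#' extrapolated beyond the band when no crossing is observed, capped at
#' 64 Hz); the dynamic compliance `Cdyn = -1/(2 pi 4 X4)` (reported `NA`
#' when the 4-Hz reactance is non-negative); the reactance area `Ax`
#' (trapezoidal integral of the negative reactance from 4 Hz to
#' `min(Fr, 32)` on the measured grid, the interpolated crossing included
#' as a node); and the 4-Hz impedance modulus `Z4 = sqrt(R4^2 + X4^2)`.
#'
#' @param spectrum an [impedance_spectrum()] covering 4-32 Hz with a 4-Hz
#'   point.
#' @param fr_cap extrapolation cap for `Fr`, Hz.
#' @return Named list with `Xm`, `Fr`, `Cdyn`, `Ax`, `Z4`.
#' @export
reactance_features <- function(spectrum, fr_cap = 64) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  in_band <- spectrum$frequency_hz >= 4 & spectrum$frequency_hz <= 32
  freq <- spectrum$frequency_hz[in_band]
  x <- spectrum$reactance[in_band]
  r <- spectrum$resistance[in_band]
  i4 <- which(abs(freq - 4) < 1e-9)
  if (length(i4) != 1L)
    stop_oscml("spectrum grid is missing the 4 Hz point")
  X4 <- x[i4]; R4 <- r[i4]
  Xm <- mean(x)
  Fr <- reactance_crossing(freq, x, cap = fr_cap)
  Cdyn <- if (X4 >= 0) NA_real_ else -1 / (2 * pi * 4 * X4)
  # integrate max(0, -X) from 4 Hz to the crossing (or band top)
  stop_f <- min(Fr, max(freq))
  grid_f <- freq[freq >= 4 & freq <= stop_f]
  grid_x <- x[freq >= 4 & freq <= stop_f]
  if (Fr > 4 && Fr < max(freq) && !any(abs(grid_f - Fr) < 1e-9)) {
    grid_f <- c(grid_f, Fr)
    grid_x <- c(grid_x, 0)
  }
  neg <- pmax(0, -grid_x)
  Ax <- if (length(grid_f) < 2L) 0 else
    sum(diff(grid_f) * (head(neg, -1) + neg[-1]) / 2)
  list(Xm = Xm, Fr = Fr, Cdyn = Cdyn, Ax = Ax, Z4 = sqrt(R4^2 + X4^2))
}

#' The eleven FOT indexes of a spectrum
#'
#' Bundles [resistance_line()], [point_resistances()] and
#' [reactance_features()] into the canonical 11-index record:
#' `R0, S, Rm, R4, R20, R4_R20, Xm, Fr, Cdyn, Ax, Z4`.
#'
#' @param spectrum an [impedance_spectrum()].
#' @param ... passed to [reactance_features()].
#' @return Named list of the 11 indexes, in canonical order.
#' @examples
#' sp <- eric_impedance(eric_params(2, 1, 0.008, 0.02))
#' unlist(fot_features(sp))
#' @export
fot_features <- function(spectrum, ...) {
  c(resistance_line(spectrum),
    point_resistances(spectrum),
    reactance_features(spectrum, ...))[fot_feature_names()]
}

#' Canonical feature-name orders
#'
#' `fot_feature_names()` returns the 11 oscillometric indexes;
#' `feature_names()` the full 16-column order (11 FOT indexes followed by
#' the five eRIC components) used by every feature table in the package.
#' @return Character vector of feature names.
#' @export
fot_feature_names <- function()
  c("R0", "S", "Rm", "R4", "R20", "R4_R20", "Xm", "Fr", "Cdyn", "Ax", "Z4")

#' @rdname fot_feature_names
#' @export
feature_names <- function() c(fot_feature_names(), "R", "Rp", "I", "C", "Rt")
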