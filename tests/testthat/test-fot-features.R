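make_spectrum <- function(f = default_frequencies(),
                          r = rep(3, length(f)),
                          x = (f - 12) / 10) impedance_spectrum(f, r, x)

test_that("resistance line recovers exact linear and constant inputs", {
  f <- default_frequencies()
  # constant resistance
  rl <- resistance_line(make_spectrum(r = rep(4.2, length(f))))
  expect_equal(rl$R0, 4.2)
  expect_equal(rl$S, 0)
  expect_equal(rl$Rm, 4.2)
  # exact line 5 - 0.1 f over the 4-16 Hz points
  sp <- make_spectrum(r = 5 - 0.1 * f)
  rl <- resistance_line(sp)
  expect_equal(rl$R0, 5, tolerance = 1e-12)
  expect_equal(rl$S, -0.1, tolerance = 1e-12)
  in_band <- f >= 4 & f <= 16
  expect_equal(rl$Rm, mean(5 - 0.1 * f[in_band]), tolerance = 1e-12)
})

test_that("resistance slope is negative on spectra with a compliant periphery", {
  set.seed(3)
  for (i in 1:20) {
    p <- random_eric_params()
    rl <- resistance_line(eric_impedance(p))
    expect_lt(rl$S, 0)
  }
})

test_that("resistance line demands two in-band points", {
  sp <- impedance_spectrum(c(18, 20, 24), c(3, 3, 3), c(0, 0, 0))
  expect_error(resistance_line(sp), "4-16")
})

test_that("point resistances are exact lookups with a clear missing-grid error", {
  rl <- point_resistances(make_spectrum(r = rep(2.5, 15)))
  expect_equal(rl$R4, 2.5)
  expect_equal(rl$R20, 2.5)
  expect_equal(rl$R4_R20, 0)
  p <- eric_params(2, 3, 0.01, 0.02)
  pr <- point_resistances(eric_impedance(p))
  expect_gt(pr$R4, pr$R20)
  expect_equal(pr$R4_R20, pr$R4 - pr$R20)
  sp <- impedance_spectrum(c(4, 8, 12), c(1, 1, 1), c(0, 0, 0))
  expect_error(point_resistances(sp), "20")
})

test_that("reactance features honour their defining identities", {
  f <- default_frequencies()
  # all-positive reactance: no negative area, resonance at the band floor
  rf <- reactance_features(make_spectrum(x = rep(0.3, 15)))
  expect_equal(rf$Ax, 0)
  expect_equal(rf$Fr, 4)
  expect_true(is.na(rf$Cdyn))
  # Cdyn plug-in inversion
  x <- (f - 12) / 10
  x[1] <- -1 / (8 * pi)
  rf <- reactance_features(impedance_spectrum(f, rep(3, 15), x))
  expect_equal(rf$Cdyn, 1.0, tolerance = 1e-12)
  expect_equal(rf$Z4, sqrt(9 + (1 / (8 * pi))^2), tolerance = 1e-12)
  expect_equal(rf$Xm, mean(x), tolerance = 1e-12)
})

test_that("resonant frequency interpolation and area match analytic and quadrature oracles", {
  set.seed(21)
  dense <- seq(4, 32, by = 0.1)
  for (i in 1:15) {
    p <- random_eric_params(sdlog = 0.3)
    fr_true <- resonant_frequency_analytic(p)
    if (is.na(fr_true) || fr_true < 4.5 || fr_true > 30) next
    sp <- eric_impedance(p, dense)
    rf <- reactance_features(sp)
    expect_lt(abs(rf$Fr - fr_true), 0.05)
    # quadrature oracle from independent complex-circuit arithmetic
    # (integrate() passes unordered nodes)
    x_of <- function(f) {
      w <- 2 * pi * f
      zc <- 1 / (1i * w * p$C)
      Im(p$R + 1i * w * p$I + (p$Rp * zc) / (p$Rp + zc))
    }
    ax_oracle <- integrate(function(f) pmax(0, -x_of(f)), 4, fr_true,
                           rel.tol = 1e-10)$value
    expect_lt(abs(rf$Ax - ax_oracle) / ax_oracle, 0.01)
  }
})

test_that("Fr extrapolates from the band top and is capped", {
  f <- default_frequencies()
  # reactance stays negative, rising: crossing extrapolated past 32 Hz
  sp <- impedance_spectrum(f, rep(3, 15), (f - 40) / 20)
  rf <- reactance_features(sp)
  expect_equal(rf$Fr, 40, tolerance = 1e-9)
  # nearly flat negative reactance: extrapolation capped
  sp2 <- impedance_spectrum(f, rep(3, 15), -1 + f * 1e-4)
  rf2 <- reactance_features(sp2)
  expect_equal(rf2$Fr, 64)
})

test_that("feature extraction ignores frequencies above 32 Hz", {
  p <- eric_params(2, 1.1, 0.006, 0.022)
  base <- eric_impedance(p, default_frequencies())
  extended <- eric_impedance(p, c(default_frequencies(), 36, 40, 48))
  expect_equal(fot_features(base), fot_features(extended), tolerance = 1e-12)
})

test_that("all 11 features are finite and self-consistent on eRIC spectra", {
  set.seed(17)
  for (i in 1:25) {
    p <- random_eric_params(sdlog = 0.3)
    sp <- eric_impedance(p)
    ft <- fot_features(sp)
    expect_named(ft, fot_feature_names())
    expect_equal(ft$R4_R20, ft$R4 - ft$R20)
    x4 <- sp$reactance[1]
    expect_equal(ft$Z4, sqrt(sp$resistance[1]^2 + x4^2))
    expect_gte(ft$Ax, 0)
    if (x4 < 0) {
      expect_gt(ft$Ax, 0)
      expect_true(all(is.finite(unlist(ft))))
    } else {
      expect_equal(ft$Ax, 0)
    }
    # the intercept tracks total resistance from below, overshooting the
    # concave low-frequency shoulder by at most a few percent; R20 >= R
    expect_lte(ft$R0, p$Rt * 1.05)
    expect_gte(ft$R20, p$R - 1e-9)
  }
})
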