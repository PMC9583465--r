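#' eRIC model parameters
#'
#' Constructs a validated parameter set for the extended RIC (eRIC)
#' two-compartment electrical analog of the respiratory system: a central
#' resistance `R` in series with an inertance `I`, followed by a peripheral
#' resistance `Rp` in parallel with a compliance `C`. The total resistance
#' `Rt = R + Rp` is stored as a derived component.
#'
#' @param R central (airway) resistance, cmH2O.s/L; must be >= 0.
#' @param Rp peripheral resistance, cmH2O.s/L; must be >= 0.
#' @param I respiratory inertance, cmH2O.s^2/L; must be >= 0.
#' @param C respiratory compliance, L/cmH2O; must be > 0.
#' @return An object of class `eric_params`: a named list with components
#'   `R`, `Rp`, `I`, `C` and the derived `Rt`.
#' @examples
#' eric_params(R = 2, Rp = 1, I = 0.008, C = 0.02)
#' @export
eric_params <- function(R, Rp, I, C) {
  check_number(R, "R", 0)
  check_number(Rp, "Rp", 0)
  check_number(I, "I", 0)
  check_number(C, "C", 0, strict = TRUE)
  structure(list(R = R, Rp = Rp, I = I, C = C, Rt = R + Rp),
            class = "eric_params")
}

#' @export
print.eric_params <- function(x, ...) {
  cat(sprintf(
    "eRIC parameters: R = %.4g, Rp = %.4g cmH2O.s/L; I = %.4g cmH2O.s2/L; C = %.4g L/cmH2O (Rt = %.4g)\n",
    x$R, x$Rp, x$I, x$C, x$Rt))
  invisible(x)
}

#' Impedance spectrum container
#'
#' A tabulated complex respiratory impedance: resistance (real part) and
#' reactance (imaginary part) on a strictly increasing frequency grid.
#'
#' @param frequencies frequencies in Hz, strictly increasing, all > 0.
#' @param resistance real part of the impedance per frequency, cmH2O.s/L.
#' @param reactance imaginary part per frequency, cmH2O.s/L.
#' @return An object of class `impedance_spectrum` (a data.frame with
#'   columns `frequency_hz`, `resistance`, `reactance`).
#' @export
impedance_spectrum <- function(frequencies, resistance, reactance) {
  if (length(frequencies) != length(resistance) ||
      length(frequencies) != length(reactance))
    stop_oscml("frequencies, resistance and reactance must have equal lengths")
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop_oscml("frequencies must be positive and finite; offending value(s): ",
               paste(frequencies[!is.finite(frequencies) | frequencies <= 0],
                     collapse = ", "))
  if (any(diff(frequencies) <= 0))
    stop_oscml("frequencies must be strictly increasing")
  structure(data.frame(frequency_hz = frequencies,
                       resistance = resistance,
                       reactance = reactance),
            class = c("impedance_spectrum", "data.frame"))
}

#' Default measurement grid
#'
#' Multiples of 2 Hz in the 4-32 Hz band: the 15-point grid used by
#' multi-frequency oscillometry protocols.
#' @return Numeric vector of frequencies in Hz.
#' @export
default_frequencies <- function() seq(4, 32, by = 2)

#' Forward eRIC impedance
#'
#' Evaluates the complex input impedance of the eRIC circuit at the given
#' frequencies:
#' \deqn{Z(\omega) = R + \frac{R_p}{1 + (\omega R_p C)^2}
#'   + j\left(\omega I - \frac{\omega R_p^2 C}{1 + (\omega R_p C)^2}\right)}
#' with \eqn{\omega = 2\pi f}. The real part decreases monotonically from
#' `R + Rp` (low frequency) towards `R`; the imaginary part is dominated by
#' the compliant branch at low frequency (negative reactance) and by the
#' inertance at high frequency.
#'
#' @param params an [eric_params()] object.
#' @param frequencies frequencies in Hz, all > 0.
#' @return An [impedance_spectrum()] on the given grid.
#' @examples
#' eric_impedance(eric_params(2, 1, 0.008, 0.02), default_frequencies())
#' @export
eric_impedance <- function(params, frequencies = default_frequencies()) {
  stopifnot(inherits(params, "eric_params"))
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop_oscml("frequencies must be positive; offending value(s): ",
               paste(frequencies[!is.finite(frequencies) | frequencies <= 0],
                     collapse = ", "))
  w <- 2 * pi * frequencies
  den <- 1 + (w * params$Rp * params$C)^2
  re <- params$R + params$Rp / den
  im <- w * params$I - w * params$Rp^2 * params$C / den
  impedance_spectrum(frequencies, re, im)
}

#' Closed-form resonant frequency of the eRIC model
#'
#' The resonant frequency is the frequency at which reactance crosses zero
#' (inertial and elastic contributions cancel). For the eRIC circuit it has
#' the closed form
#' \deqn{f_r = \frac{1}{2\pi}\sqrt{\frac{R_p^2 C - I}{I R_p^2 C^2}}}
#' which exists only when \eqn{R_p^2 C > I} and \eqn{I > 0}; otherwise the
#' reactance never crosses zero and `NA` is returned.
#'
#' @param params an [eric_params()] object.
#' @return Resonant frequency in Hz, or `NA_real_` when no real root exists.
#' @export
resonant_frequency_analytic <- function(params) {
  stopifnot(inherits(params, "eric_params"))
  num <- params$Rp^2 * params$C - params$I
  if (params$I <= 0 || num <= 0) return(NA_real_)
  sqrt(num / (params$I * params$Rp^2 * params$C^2)) / (2 * pi)
}

#' Cohort simulation configuration
#'
#' Describes a synthetic three-group oscillometry study: a control group and
#' two disease groups (normal and altered spirometry). Per-group eRIC
#' parameters are drawn from log-normal distributions (positivity and the
#' right-skewed, outlier-prone shape typical of clinical oscillometry);
#' the disease effect is a multiplicative shift of the group median.
#' Replicate spectra receive independent multiplicative Gaussian noise on
#' both impedance parts, and each subject keeps the arithmetic mean of the
#' replicates, mirroring the three-measurement averaging protocol.
#'
#' @param n_control,n_disease_normal,n_disease_altered group sizes.
#' @param replicates replicate spectra per subject (averaged).
#' @param noise_sd relative (multiplicative) replicate noise standard
#'   deviation, applied independently per frequency to resistance and
#'   reactance.
#' @param control_median named list of the control-group median parameters
#'   (`R`, `Rp`, `I`, `C`).
#' @param shift_normal,shift_altered named lists of multiplicative median
#'   shifts for the two disease groups. The defaults raise Rp and lower C
#'   with disease, which raises total resistance, resonant frequency,
#'   reactance area and 4-Hz impedance modulus and lowers dynamic
#'   compliance.
#' @param sdlog_control,sdlog_disease log-scale dispersion of the parameter
#'   distributions.
#' @param frequencies measurement grid in Hz.
#' @param seed integer random seed; cohort generation is a pure function of
#'   the configuration including this seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 25L,
                          n_disease_normal = 24L,
                          n_disease_altered = 23L,
                          replicates = 3L,
                          noise_sd = 0.05,
                          control_median = list(R = 2.0, Rp = 1.1,
                                                I = 0.006, C = 0.022),
                          shift_normal = list(R = 1.10, Rp = 1.35,
                                              I = 1.00, C = 0.70),
                          shift_altered = list(R = 1.15, Rp = 1.55,
                                               I = 1.05, C = 0.58),
                          sdlog_control = 0.25,
                          sdlog_disease = 0.30,
                          frequencies = default_frequencies(),
                          seed = 7L) {
  for (n in c(n_control, n_disease_normal, n_disease_altered, replicates))
    check_number(n, "group size / replicates", 1)
  check_number(noise_sd, "noise_sd", 0)
  check_number(sdlog_control, "sdlog_control", 0)
  check_number(sdlog_disease, "sdlog_disease", 0)
  for (nm in c("R", "Rp", "I", "C")) {
    check_number(control_median[[nm]], paste0("control_median$", nm), 0)
    check_number(shift_normal[[nm]], paste0("shift_normal$", nm), 0)
    check_number(shift_altered[[nm]], paste0("shift_altered$", nm), 0)
  }
  structure(list(n_control = as.integer(n_control),
                 n_disease_normal = as.integer(n_disease_normal),
                 n_disease_altered = as.integer(n_disease_altered),
                 replicates = as.integer(replicates),
                 noise_sd = noise_sd,
                 control_median = control_median,
                 shift_normal = shift_normal,
                 shift_altered = shift_altered,
                 sdlog_control = sdlog_control,
                 sdlog_disease = sdlog_disease,
                 frequencies = frequencies,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

draw_params <- function(median, sdlog) {
  eric_params(R = rlnorm(1, log(median$R), sdlog),
              Rp = rlnorm(1, log(median$Rp), sdlog),
              I = rlnorm(1, log(median$I), sdlog),
              C = rlnorm(1, log(median$C), sdlog))
}

#' Simulate a synthetic oscillometry cohort
#'
#' Draws per-subject eRIC parameters from the group's log-normal
#' distribution, generates `replicates` noisy spectra per subject from the
#' forward model, and stores the replicate-averaged spectrum alongside the
#' true generating parameters.
#'
#' @param config a [cohort_config()].
#' @return A list of class `oscml_cohort`; each element is a `subject_record`
#'   list with fields `subject_id`, `group` (one of `"control"`,
#'   `"disease_normal"`, `"disease_altered"`), `label` (`"control"` or
#'   `"disease"`), `spectrum` (replicate-averaged [impedance_spectrum()]),
#'   `replicate_spectra` and `true_params`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 1))
#' length(cohort)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seed(config$seed, "simulate_cohort"))
  groups <- c(rep("control", config$n_control),
              rep("disease_normal", config$n_disease_normal),
              rep("disease_altered", config$n_disease_altered))
  freqs <- config$frequencies
  cohort <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    med <- switch(g,
      control = config$control_median,
      disease_normal = Map(`*`, config$control_median, config$shift_normal),
      disease_altered = Map(`*`, config$control_median, config$shift_altered))
    sdlog <- if (g == "control") config$sdlog_control else config$sdlog_disease
    params <- draw_params(med, sdlog)
    clean <- eric_impedance(params, freqs)
    reps <- vector("list", config$replicates)
    for (r in seq_len(config$replicates)) {
      re <- clean$resistance * (1 + rnorm(length(freqs), 0, config$noise_sd))
      im <- clean$reactance * (1 + rnorm(length(freqs), 0, config$noise_sd))
      reps[[r]] <- impedance_spectrum(freqs, re, im)
    }
    avg_re <- rowMeans(sapply(reps, `[[`, "resistance"))
    avg_im <- rowMeans(sapply(reps, `[[`, "reactance"))
    cohort[[i]] <- structure(
      list(subject_id = sprintf("S%03d", i),
           group = g,
           label = if (g == "control") "control" else "disease",
           spectrum = impedance_spectrum(freqs, avg_re, avg_im),
           replicate_spectra = reps,
           true_params = params),
      class = "subject_record")
  }
  structure(cohort, class = "oscml_cohort")
}

#' Write / read a cohort as plain CSV files
#'
#' The on-disk form is two CSV files: a long spectra table
#' (`subject_id, replicate, frequency_hz, resistance, reactance`; replicate 0
#' is the stored average) and a labels table (`subject_id, group`).
#'
#' @param cohort an `oscml_cohort`.
#' @param spectra_file,labels_file output/input CSV paths.
#' @return `write_cohort` returns the paths invisibly; `read_cohort` returns
#'   an `oscml_cohort` (without true parameters, which only the simulator
#'   knows).
#' @export
write_cohort <- function(cohort, spectra_file, labels_file) {
  stopifnot(inherits(cohort, "oscml_cohort"))
  rows <- lapply(cohort, function(s) {
    reps <- c(list(s$spectrum), s$replicate_spectra)
    do.call(rbind, lapply(seq_along(reps), function(k) {
      sp <- reps[[k]]
      data.frame(subject_id = s$subject_id, replicate = k - 1L,
                 frequency_hz = sp$frequency_hz,
                 resistance = sp$resistance, reactance = sp$reactance)
    }))
  })
  write.csv(do.call(rbind, rows), spectra_file, row.names = FALSE)
  labels <- data.frame(subject_id = vapply(cohort, `[[`, "", "subject_id"),
                       group = vapply(cohort, `[[`, "", "group"))
  write.csv(labels, labels_file, row.names = FALSE)
  invisible(c(spectra_file, labels_file))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(spectra_file, labels_file) {
  spectra <- read.csv(spectra_file)
  labels <- read.csv(labels_file)
  cohort <- lapply(seq_len(nrow(labels)), function(i) {
    id <- labels$subject_id[i]
    sub <- spectra[spectra$subject_id == id, ]
    avg <- sub[sub$replicate == 0L, ]
    reps <- lapply(setdiff(unique(sub$replicate), 0L), function(r) {
      s <- sub[sub$replicate == r, ]
      impedance_spectrum(s$frequency_hz, s$resistance, s$reactance)
    })
    structure(list(subject_id = id, group = labels$group[i],
                   label = if (labels$group[i] == "control") "control"
                           else "disease",
                   spectrum = impedance_spectrum(avg$frequency_hz,
                                                 avg$resistance,
                                                 avg$reactance),
                   replicate_spectra = reps,
                   true_params = NULL),
              class = "subject_record")
  })
  structure(cohort, class = "oscml_cohort")
}
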