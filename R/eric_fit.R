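#' Fit the eRIC model to a measured spectrum
#'
#' Estimates the four eRIC components from an impedance spectrum by bounded
#' damped (Levenberg-Marquardt) nonlinear least squares on the stacked
#' residuals of the real and imaginary parts, weighted equally. The loss
#' surface carries mirror local minima in the `(Rp, C)` pair, so the solver
#' is restarted from a fixed multi-start list built from resistance-curve
#' heuristics (low/high-frequency resistances splitting `R` vs `Rp`) crossed
#' with coarse `(I, C)` guesses; the start with the lowest residual wins.
#' All parameters are bounded below by 0 (`C` by a small positive floor),
#' and the procedure is deterministic for a fixed spectrum.
#'
#' @param spectrum an [impedance_spectrum()] with at least 4 points.
#' @param c_floor lower bound for the compliance, L/cmH2O.
#' @param max_iter per-start iteration cap.
#' @return An object of class `eric_fit`: list with `params`
#'   ([eric_params()]), `rss` (residual sum of squares), `converged`,
#'   `iterations`, and `start` (the winning start point).
#' @examples
#' truth <- eric_params(1.5, 4, 0.008, 0.015)
#' fit <- fit_eric(eric_impedance(truth))
#' fit$params
#' @export
fit_eric <- function(spectrum, c_floor = 1e-6, max_iter = 200L) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  if (nrow(spectrum) < 4L)
    stop_oscml("fit_eric needs at least 4 frequency points (4 free parameters)")
  f <- spectrum$frequency_hz
  obs <- c(spectrum$resistance, spectrum$reactance)
  resid_fun <- function(p) {
    w <- 2 * pi * f
    den <- 1 + (w * p[2] * p[4])^2
    c(p[1] + p[2] / den, w * p[3] - w * p[2]^2 * p[4] / den) - obs
  }

  starts <- eric_start_points(spectrum)
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fun,
                         lower = c(0, 0, 0, c_floor),
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    conv <- res$info %in% 1:4
    if (is.null(best) || rss < best$rss)
      best <- list(par = res$par, rss = rss, converged = conv,
                   iterations = res$niter, start = s)
  }
  if (is.null(best))
    return(structure(list(params = NULL, rss = Inf, converged = FALSE,
                          iterations = 0L, start = NULL),
                     class = "eric_fit"))
  p <- best$par
  structure(list(params = eric_params(p[1], p[2], p[3], max(p[4], c_floor)),
                 rss = best$rss, converged = best$converged,
                 iterations = best$iterations, start = best$start),
            class = "eric_fit")
}

# Fixed multi-start list from spectrum heuristics. R + Rp must total roughly
# the low-frequency resistance; the split between them is ambiguous before
# fitting, hence a coarse grid of split fractions crossed with I guesses
# from the high-frequency reactance and C guesses bracketing typical
# respiratory compliances.
eric_start_points <- function(spectrum) {
  f <- spectrum$frequency_hz
  r <- spectrum$resistance
  x <- spectrum$reactance
  r_lo <- max(r[1], 1e-3)
  i_hi <- max(x[length(x)] / (2 * pi * f[length(f)]), 1e-4)
  starts <- list()
  for (split in c(0.3, 0.6, 0.9)) {
    for (Cg in c(0.005, 0.02, 0.08)) {
      for (Ig in unique(c(i_hi, 0.008))) {
        starts[[length(starts) + 1L]] <-
          c(split * r_lo, max((1 - split) * r_lo, 1e-3), Ig, Cg)
      }
    }
  }
  starts
}

#' @export
print.eric_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("eRIC fit: did not converge from any start\n")
  } else {
    cat(sprintf("eRIC fit (rss = %.4g, converged = %s):\n", x$rss,
                x$converged))
    print(x$params)
  }
  invisible(x)
}

#' Assemble the 16-feature record
#'
#' Combines the 11 FOT indexes with the five eRIC components (`R`, `Rp`,
#' `I`, `C`, `Rt`) into the fixed-order 16-feature record that every
#' classifier in the package consumes.
#'
#' @param fot list from [fot_features()].
#' @param fit an `eric_fit` from [fit_eric()].
#' @return Named numeric vector of length 16 in [feature_names()] order,
#'   with attribute `converged` from the fit.
#' @export
assemble_features <- function(fot, fit) {
  stopifnot(inherits(fit, "eric_fit"))
  if (is.null(fit$params))
    stop_oscml("cannot assemble features from a fit with no parameter estimate")
  rec <- c(unlist(fot[fot_feature_names()]),
           R = fit$params$R, Rp = fit$params$Rp, I = fit$params$I,
           C = fit$params$C, Rt = fit$params$Rt)
  stopifnot(identical(names(rec), feature_names()))
  attr(rec, "converged") <- fit$converged
  rec
}

#' Feature table for a whole cohort
#'
#' Runs feature extraction and eRIC inversion on every subject's averaged
#' spectrum and returns the classifier-ready table.
#'
#' When the 4-Hz reactance is non-negative (resonance below the measured
#' band, a very compliant extreme) the dynamic compliance is undefined;
#' under the default `cdyn_policy = "cap"` it is replaced by the value at a
#' 4-Hz reactance of -0.01 cmH2O.s/L (about 0.40 L/cmH2O), an upper cap
#' consistent with the direction of the degeneracy; `"na"` keeps the
#' missing value.
#'
#' @param cohort an `oscml_cohort`.
#' @param cdyn_policy how to handle an undefined dynamic compliance.
#' @return A data.frame with `subject_id`, `group`, `label`, the 16 features
#'   in canonical order, and a `fit_converged` flag.
#' @export
cohort_features <- function(cohort, cdyn_policy = c("cap", "na")) {
  stopifnot(inherits(cohort, "oscml_cohort"))
  cdyn_policy <- match.arg(cdyn_policy)
  rows <- lapply(cohort, function(s) {
    fit <- fit_eric(s$spectrum)
    fot <- fot_features(s$spectrum)
    if (is.na(fot$Cdyn) && cdyn_policy == "cap")
      fot$Cdyn <- -1 / (2 * pi * 4 * (-0.01))
    rec <- assemble_features(fot, fit)
    cbind(data.frame(subject_id = s$subject_id, group = s$group,
                     label = s$label),
          as.data.frame(as.list(rec)),
          data.frame(fit_converged = isTRUE(attr(rec, "converged"))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a feature table as CSV
#'
#' Plain-text round trip for the 16-feature table; numeric columns are
#' written with full precision so that the round trip is bit-identical.
#'
#' @param features data.frame from [cohort_features()].
#' @param file CSV path.
#' @return `write_features` the path invisibly; `read_features` the table.
#' @export
write_features <- function(features, file) {
  num <- vapply(features, is.numeric, TRUE)
  out <- features
  out[num] <- lapply(features[num], function(x) sprintf("%.17g", x))
  write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_features
#' @export
read_features <- function(file) {
  out <- read.csv(file, stringsAsFactors = FALSE)
  for (nm in intersect(names(out), feature_names()))
    out[[nm]] <- as.numeric(out[[nm]])
  out
}
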