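#' Dead-time corrected travelling-wave drift time
#'
#' Standard TW calibration correction for the m/z-dependent transit time
#' outside the mobility cell: `t' = td - edc * sqrt(mz) / 1000` (ms), with
#' the instrument-specific EDC (enhanced duty cycle) delay coefficient.
#'
#' @param td measured drift time(s), ms.
#' @param mz ion m/z.
#' @param edc_coefficient instrument EDC delay coefficient (0 disables the
#'   correction).
#' @return corrected drift time(s), ms; errors if the correction drives a
#'   drift time to zero or below.
#' @export
corrected_drift_time <- function(td, mz, edc_coefficient = 0) {
  if (any(td <= 0)) stop("drift times must be > 0")
  tp <- td - edc_coefficient * sqrt(mz) / 1000
  if (any(tp <= 0)) stop("corrected drift time <= 0: unphysical EDC correction")
  tp
}

#' Charge/reduced-mass normalized collision cross section
#'
#' `ccs' = ccs * sqrt(mu) / z` with reduced mass
#' `mu = m * m_gas / (m + m_gas)`; the standard normalization that makes
#' calibrant cross sections of different charge and mass fall on one
#' power law in corrected drift time.
#'
#' @param ccs cross section(s), A^2.
#' @param z charge state.
#' @param neutral_mass ion neutral mass, u.
#' @param gas_mass buffer gas mass, u; default nitrogen (28.0134).
#' @return normalized cross section(s).
#' @export
corrected_ccs <- function(ccs, z, neutral_mass, gas_mass = 28.0134) {
  if (any(c(ccs, z, neutral_mass, gas_mass) <= 0)) stop("inputs must be positive")
  mu <- neutral_mass * gas_mass / (neutral_mass + gas_mass)
  ccs * sqrt(mu) / z
}

#' Fit a travelling-wave CCS calibration
#'
#' Fits the relation between corrected drift time and normalized cross
#' section over a calibrant table, in either of the two published dialects:
#' the logarithmic (power-law) form `ln ccs' = ln a + b ln t'` (default) or
#' the linear form `ccs' = a + b t'`.
#'
#' @param calibrants data.frame with columns `name`, `z`, `neutral_mass`,
#'   `published_ccs` (A^2) and `drift_time` (ms).
#' @param mode `"log"` (power law, default) or `"linear"`.
#' @param edc_coefficient EDC delay coefficient for the drift-time
#'   correction; no hidden default beyond 0.
#' @param gas_mass buffer gas mass, u (nitrogen by default).
#' @return list of class `ccs_calibration` with `mode`, `intercept`
#'   (ln a resp. a), `slope` (the exponent resp. linear slope),
#'   `r_squared`, `edc_coefficient`, `gas_mass` and the corrected
#'   drift-time range used.
#' @export
fit_calibration <- function(calibrants, mode = c("log", "linear"),
                            edc_coefficient = 0, gas_mass = 28.0134) {
  mode <- match.arg(mode)
  need <- c("z", "neutral_mass", "published_ccs", "drift_time")
  if (!all(need %in% names(calibrants)))
    stop("calibrant table must have columns ", paste(need, collapse = ", "))
  if (nrow(calibrants) < 2) stop("need >= 2 calibrant points")
  mz <- (calibrants$neutral_mass + calibrants$z * .proton_mass) / calibrants$z
  tp <- corrected_drift_time(calibrants$drift_time, mz, edc_coefficient)
  if (length(unique(tp)) < 2) stop("singular design: corrected drift times coincide")
  op <- corrected_ccs(calibrants$published_ccs, calibrants$z,
                      calibrants$neutral_mass, gas_mass)
  m <- if (mode == "log") stats::lm(log(op) ~ log(tp)) else stats::lm(op ~ tp)
  co <- stats::coef(m)
  yy <- if (mode == "log") log(op) else op
  structure(list(mode = mode,
                 intercept = unname(co[1]), slope = unname(co[2]),
                 r_squared = .lm_r2(m, yy),
                 edc_coefficient = edc_coefficient,
                 gas_mass = gas_mass,
                 tp_range = range(tp),
                 n = nrow(calibrants)),
            class = "ccs_calibration")
}

#' @export
print.ccs_calibration <- function(x, ...) {
  if (x$mode == "log")
    cat(sprintf("<ccs_calibration log-log> exponent = %.4f, ln a = %.4f, R^2 = %.5f (n = %d)\n",
                x$slope, x$intercept, x$r_squared, x$n))
  else
    cat(sprintf("<ccs_calibration linear> slope = %.4f, intercept = %.4f, R^2 = %.5f (n = %d)\n",
                x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Convert an analyte drift time to a calibrated CCS
#'
#' Evaluates the fitted calibration at the corrected drift time and inverts
#' the charge/reduced-mass normalization.  Deterministic; drift times outside
#' the calibrated range trigger an extrapolation warning, not an error.
#'
#' @param cal a `ccs_calibration`.
#' @param td drift time(s), ms.
#' @param mz ion m/z (for the dead-time correction).
#' @param z charge state.
#' @param neutral_mass ion neutral mass, u.
#' @return CCS value(s) in A^2.
#' @export
apply_calibration <- function(cal, td, mz, z, neutral_mass) {
  stopifnot(inherits(cal, "ccs_calibration"))
  tp <- corrected_drift_time(td, mz, cal$edc_coefficient)
  if (any(tp < cal$tp_range[1] | tp > cal$tp_range[2]))
    warning("drift time outside calibrated range: extrapolating")
  op <- if (cal$mode == "log") exp(cal$intercept + cal$slope * log(tp))
        else cal$intercept + cal$slope * tp
  mu <- neutral_mass * cal$gas_mass / (neutral_mass + cal$gas_mass)
  op * z / sqrt(mu)
}

#' Drift-time peak statistics
#'
#' Intensity-weighted centroid and standard deviation of an arrival-time
#' profile, plus the full width at half maximum obtained by linear
#' interpolation of the half-maximum crossings.  For a profile with a single
#' nonzero bin the FWHM is reported as one grid spacing (documented
#' convention for the degenerate case).
#'
#' @param drift_time profile grid, ms (>= 3 points, increasing).
#' @param intensity non-negative intensities on the grid.
#' @return list with `mean`, `sd`, `fwhm` (ms).
#' @export
drift_peak_stats <- function(drift_time, intensity) {
  if (length(drift_time) < 3) stop("need >= 3 profile points")
  if (length(drift_time) != length(intensity)) stop("length mismatch")
  if (any(intensity < 0)) stop("negative intensity")
  if (sum(intensity) == 0) stop("all-zero profile")
  o <- order(drift_time)
  x <- drift_time[o]; y <- intensity[o]
  w <- y / sum(y)
  m <- sum(w * x)
  s <- sqrt(sum(w * (x - m)^2))

  half <- max(y) / 2
  imax <- which.max(y)
  grid <- stats::median(diff(x))
  above <- y >= half
  # left crossing
  left <- x[imax]
  for (i in seq(imax, 2)) {
    if (y[i - 1] < half) {
      left <- x[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
      break
    }
    left <- x[i - 1]
  }
  right <- x[imax]
  n <- length(x)
  if (imax < n) for (i in seq(imax, n - 1)) {
    if (y[i + 1] < half) {
      right <- x[i] + (y[i] - half) / (y[i] - y[i + 1]) * (x[i + 1] - x[i])
      break
    }
    right <- x[i + 1]
  }
  fwhm <- right - left
  if (sum(y > 0) == 1) fwhm <- grid
  list(mean = m, sd = s, fwhm = fwhm)
}

#' Mobility summary for a set of analyte drift profiles
#'
#' Produces a drift-time/CCS summary table (one row per analyte) from
#' replicate arrival-time profiles: per-replicate centroids are averaged,
#' their spread reported as the drift-time standard deviation, the FWHM is
#' the mean replicate FWHM, and the centroids are converted to CCS through
#' the supplied calibration.
#'
#' @param profiles named list (one element per analyte) of lists of
#'   data.frames with columns `drift_time`, `intensity` (one per replicate).
#' @param meta data.frame with columns `analyte`, `z`, `neutral_mass`
#'   matching the profile names.
#' @param cal a `ccs_calibration`.
#' @return data.frame with columns `analyte`, `dt_mean`, `dt_sd`, `fwhm`,
#'   `ccs_mean`, `ccs_sd`.
#' @export
mobility_table <- function(profiles, meta, cal) {
  stopifnot(inherits(cal, "ccs_calibration"))
  rows <- lapply(names(profiles), function(an) {
    reps <- profiles[[an]]
    info <- meta[meta$analyte == an, , drop = FALSE]
    if (nrow(info) != 1) stop("no unique metadata row for analyte ", an)
    mz <- (info$neutral_mass + info$z * .proton_mass) / info$z
    st <- lapply(reps, function(p) drift_peak_stats(p$drift_time, p$intensity))
    dts <- vapply(st, `[[`, numeric(1), "mean")
    ccs <- vapply(dts, function(dt)
      apply_calibration(cal, dt, mz, info$z, info$neutral_mass), numeric(1))
    data.frame(analyte = an,
               dt_mean = mean(dts),
               dt_sd = if (length(dts) > 1) stats::sd(dts) else 0,
               fwhm = mean(vapply(st, `[[`, numeric(1), "fwhm")),
               ccs_mean = mean(ccs),
               ccs_sd = if (length(ccs) > 1) stats::sd(ccs) else 0)
  })
  do.call(rbind, rows)
}
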