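#' Assemble a replicate-averaged survival-yield curve
#'
#' The survival yield (SY) at each collision voltage step is the normalized
#' educt fraction.  Replicates must share the same voltage schedule; the
#' function errors with the list of missing (replicate, delta_cv) pairs
#' otherwise.  For each voltage the mean and standard deviation across
#' replicates is reported (sd = 0 for a single replicate).
#'
#' @param normalized tidy data.frame from [normalize_spectra()] (columns
#'   `delta_cv`, `replicate_id`, `species`, `percent`).
#' @param educt_label species label of the surviving complex (default
#'   `"trimer"`).
#' @param analyte optional analyte name attached to the curve.
#' @return data.frame of class `sy_curve` with columns `delta_cv`, `sy_mean`,
#'   `sy_sd`, `n_replicates`, sorted by increasing voltage.
#' @export
assemble_curve <- function(normalized, educt_label = "trimer", analyte = NA_character_) {
  need <- c("delta_cv", "replicate_id", "species", "percent")
  if (!all(need %in% names(normalized)))
    stop("normalized table must have columns ", paste(need, collapse = ", "))
  ed <- normalized[normalized$species == educt_label, , drop = FALSE]
  if (nrow(ed) == 0) stop("no rows with educt species '", educt_label, "'")

  dcvs <- sort(unique(ed$delta_cv))
  if (length(dcvs) < 3) stop("need >= 3 distinct delta_cv values")
  reps <- unique(ed$replicate_id)
  full <- expand.grid(replicate_id = reps, delta_cv = dcvs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  have <- paste(ed$replicate_id, ed$delta_cv)
  missing <- full[!paste(full$replicate_id, full$delta_cv) %in% have, , drop = FALSE]
  if (nrow(missing) > 0) {
    stop("replicates are not aligned on the same delta_cv schedule; missing: ",
         paste(sprintf("(%s, %g V)", missing$replicate_id, missing$delta_cv),
               collapse = ", "))
  }

  agg <- lapply(dcvs, function(v) {
    y <- ed$percent[ed$delta_cv == v]
    data.frame(delta_cv = v, sy_mean = mean(y),
               sy_sd = if (length(y) > 1) stats::sd(y) else 0,
               n_replicates = length(y))
  })
  out <- do.call(rbind, agg)
  attr(out, "analyte") <- analyte
  attr(out, "educt") <- educt_label
  class(out) <- c("sy_curve", "data.frame")
  out
}

#' Construct a survival-yield curve directly from summary values
#'
#' For data already provided as (delta_cv, mean, sd) triples, e.g. published
#' intensity tables.
#'
#' @param delta_cv,sy_mean,sy_sd numeric vectors; `sy_sd` defaults to 0.
#' @param n_replicates replicate count per point (default 1).
#' @param analyte optional analyte name.
#' @return an `sy_curve`.
#' @export
sy_curve <- function(delta_cv, sy_mean, sy_sd = 0, n_replicates = 1L,
                     analyte = NA_character_) {
  if (any(sy_mean < 0 | sy_mean > 100)) stop("sy_mean must lie in [0, 100]")
  o <- order(delta_cv)
  if (anyDuplicated(delta_cv)) stop("delta_cv values must be distinct")
  out <- data.frame(delta_cv = delta_cv[o], sy_mean = sy_mean[o],
                    sy_sd = rep_len(sy_sd, length(delta_cv))[o],
                    n_replicates = rep_len(as.integer(n_replicates),
                                           length(delta_cv))[o])
  attr(out, "analyte") <- analyte
  class(out) <- c("sy_curve", "data.frame")
  out
}

#' Evaluate the Boltzmann sigmoid
#'
#' `y(x) = A2 + (A1 - A2) / (1 + exp((x - x0) / dx))`, the standard
#' four-parameter sigmoid describing educt decay with midpoint `x0` and
#' width `dx`.
#'
#' @param x collision voltage(s).
#' @param A1,A2 initial and final plateau (percent).
#' @param x0 midpoint voltage (the half-dissociation voltage).
#' @param dx width parameter (V), positive.
#' @return survival yield(s), percent.
#' @export
boltzmann <- function(x, A1, A2, x0, dx) {
  A2 + (A1 - A2) / (1 + exp((x - x0) / dx))
}

#' Fit a Boltzmann sigmoid to a survival-yield curve
#'
#' Least-squares fit of [boltzmann()] by Levenberg-Marquardt
#' (`minpack.lm::nlsLM`).  Initialization follows a robust scheme for
#' monotone sigmoids: A1 = max(sy), A2 = min(sy), x0 = voltage of the point
#' nearest the mid-level, dx = voltage range / 10.  Plateaus are fitted free
#' by default because residual signals (e.g. sodium adduct satellites) can
#' shift them; set `pin_plateaus = TRUE` to fix A1 = 100, A2 = 0.
#'
#' @param curve an `sy_curve` (or data.frame with `delta_cv`, `sy_mean`).
#' @param pin_plateaus fix the plateaus at 100/0 instead of fitting them.
#' @param weighted weight points by `1/sy_sd^2` (points with sd 0 get the
#'   median weight); default FALSE, matching unweighted practice.
#' @return object of class `boltzmann_fit`: list with `A1`, `A2`, `x0`, `dx`,
#'   `r_squared`, the fitted values and the input data.  `dx` is always
#'   returned positive (a fit converging to negative `dx` is re-expressed by
#'   swapping the plateaus).  Warns if the data rise instead of decay.
#' @examples
#' cv <- c(0, 2, 5, 7, 10, 12, 15, 20, 30, 40, 50)
#' fit_boltzmann(sy_curve(cv, boltzmann(cv, 100, 0, 13.5, 1.2)))
#' @export
fit_boltzmann <- function(curve, pin_plateaus = FALSE, weighted = FALSE) {
  if (!all(c("delta_cv", "sy_mean") %in% names(curve)))
    stop("curve must have delta_cv and sy_mean columns")
  x <- curve$delta_cv
  y <- curve$sy_mean
  if (length(x) < 4) stop("need >= 4 points to fit a Boltzmann sigmoid")
  if (stats::cor(x, y) > 0)
    warning("survival yield increases with delta_cv; educt should decay")

  a1 <- max(y); a2 <- min(y)
  if (stats::cor(x, y) > 0) { a1 <- min(y); a2 <- max(y) }  # rising data
  x0 <- x[which.min(abs(y - (a1 + a2) / 2))]
  dx <- diff(range(x)) / 10
  w <- rep(1, length(x))
  if (weighted && "sy_sd" %in% names(curve)) {
    sds <- curve$sy_sd
    pos <- sds > 0
    if (any(pos)) {
      w[pos] <- 1 / sds[pos]^2
      w[!pos] <- stats::median(w[pos])
    }
  }

  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    if (pin_plateaus) {
      minpack.lm::nlsLM(y ~ boltzmann(x, 100, 0, x0, dx), data = df,
                        start = list(x0 = x0, dx = dx), weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ boltzmann(x, A1, A2, x0, dx), data = df,
                        start = list(A1 = a1, A2 = a2, x0 = x0, dx = dx),
                        weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e) {
      stop(sprintf(
        "Boltzmann fit did not converge (start: A1=%.3g, A2=%.3g, x0=%.3g, dx=%.3g): %s",
        a1, a2, x0, dx, conditionMessage(e)))
    })

  p <- as.list(stats::coef(fit))
  if (pin_plateaus) { p$A1 <- 100; p$A2 <- 0 }
  # canonical orientation: dx > 0, A1 the low-voltage plateau
  if (p$dx < 0) {
    tmp <- p$A1; p$A1 <- p$A2; p$A2 <- tmp
    p$dx <- -p$dx
  }
  yhat <- boltzmann(x, p$A1, p$A2, p$x0, p$dx)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  structure(
    list(A1 = p$A1, A2 = p$A2, x0 = p$x0, dx = p$dx, r_squared = r2,
         fitted = yhat, data = df, pin_plateaus = pin_plateaus),
    class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_fit> A1 = %.2f%%, A2 = %.2f%%, x0 (dCV50) = %.3f V, dx = %.3f V, R^2 = %.5f\n",
    x$A1, x$A2, x$x0, x$dx, x$r_squared))
  invisible(x)
}

#' Tangent of the fitted Boltzmann curve at its midpoint
#'
#' The analytic tangent at `x0`: slope `(A2 - A1) / (4 dx)` (percent per
#' volt), passing through the mid-level `(A1 + A2) / 2`.
#'
#' @param fit a `boltzmann_fit`.
#' @return object of class `tangent_line`: list with `slope`, `intercept`,
#'   `anchor_x` (= x0).
#' @export
tangent_at_midpoint <- function(fit) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  slope <- (fit$A2 - fit$A1) / (4 * fit$dx)
  mid <- (fit$A1 + fit$A2) / 2
  structure(list(slope = slope, intercept = mid - slope * fit$x0,
                 anchor_x = fit$x0),
            class = "tangent_line")
}

#' Sample evenly spaced points on the midpoint tangent
#'
#' Returns `n_points` voltages evenly spaced between the voltages at which
#' the tangent line crosses the survival-yield bounds, with the linear SY
#' values.  SY is clipped into the open interval (0, 100) so that downstream
#' logarithms stay finite.
#'
#' @param fit a `boltzmann_fit`.
#' @param line the corresponding [tangent_at_midpoint()] line.
#' @param n_points number of sampled points (>= 2; default 5).
#' @param sy_bounds survival-yield window in percent, default `c(10, 90)`.
#' @return data.frame with columns `delta_cv`, `sy` (percent).
#' @export
sample_tangent <- function(fit, line = tangent_at_midpoint(fit),
                           n_points = 5L, sy_bounds = c(10, 90)) {
  stopifnot(inherits(fit, "boltzmann_fit"), inherits(line, "tangent_line"))
  if (n_points < 2) stop("n_points must be >= 2")
  lo <- min(sy_bounds); hi <- max(sy_bounds)
  if (!(lo > 0 && hi < 100 && lo < hi))
    stop("sy_bounds must satisfy 0 < low < high < 100")
  if (line$slope == 0) stop("tangent slope is zero; bounds unreachable")
  x_at <- function(yv) (yv - line$intercept) / line$slope
  xs <- seq(x_at(hi), x_at(lo), length.out = n_points)
  sy <- line$intercept + line$slope * xs
  eps <- 1e-9
  sy <- pmin(pmax(sy, eps), 100 - eps)
  data.frame(delta_cv = xs, sy = sy)
}

#' @export
plot.sy_curve <- function(x, fit = NULL, ...) {
  graphics::plot(x$delta_cv, x$sy_mean, pch = 19,
                 xlab = expression(Delta * "CV (V)"),
                 ylab = "survival yield (%)",
                 ylim = c(0, max(100, x$sy_mean)), ...)
  graphics::arrows(x$delta_cv, x$sy_mean - x$sy_sd,
                   x$delta_cv, x$sy_mean + x$sy_sd,
                   angle = 90, code = 3, length = 0.03)
  if (!is.null(fit)) {
    xx <- seq(min(x$delta_cv), max(x$delta_cv), length.out = 200)
    graphics::lines(xx, boltzmann(xx, fit$A1, fit$A2, fit$x0, fit$dx))
  }
  invisible(x)
}
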