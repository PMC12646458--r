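# Esterase kinetics: initial-rate estimation from absorbance progress
# curves, Michaelis-Menten fitting of (substrate, rate) tables with an
# upper-bound-regime diagnostic, wild-type-normalized relative activities,
# and DTNB thioesterase endpoint processing. Wavelengths are metadata:
# rates stay in absorbance units unless an extinction coefficient is
# supplied by the caller.

#' Progress curve container
#'
#' @param times numeric, strictly increasing (seconds).
#' @param absorbance numeric, same length (AU).
#' @param wavelength nm (metadata).
#' @param label curve label.
#' @return data.frame of class \code{progress_curve}.
#' @export
progress_curve <- function(times, absorbance, wavelength = NA_real_,
                           label = "") {
  times <- as.numeric(times); absorbance <- as.numeric(absorbance)
  if (length(times) != length(absorbance))
    stop("times and absorbance must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  out <- data.frame(time = times, absorbance = absorbance)
  attr(out, "wavelength") <- wavelength
  attr(out, "label") <- label
  class(out) <- c("progress_curve", "data.frame")
  out
}

#' Initial rate from a progress curve
#'
#' Ordinary least-squares slope over an early window of the curve. The
#' default window is the first 20 percent of points, with a minimum of 5.
#' A paired blank (control) curve on the same time grid is subtracted
#' before fitting when supplied.
#'
#' @param curve \code{\link{progress_curve}} or data.frame with
#'   \code{time, absorbance}.
#' @param window optional integer index range (e.g. \code{1:20}).
#' @param blank optional control curve on the same time grid.
#' @return list of class \code{rate_estimate}: \code{slope} (AU/s),
#'   \code{intercept}, \code{r2}, \code{se}, \code{window}.
#' @export
initial_rate <- function(curve, window = NULL, blank = NULL) {
  stopifnot(is.data.frame(curve), all(c("time", "absorbance") %in% names(curve)))
  n <- nrow(curve)
  if (n < 5) stop("initial_rate needs at least 5 points")
  y <- curve$absorbance
  if (!is.null(blank)) {
    if (nrow(blank) != n || max(abs(blank$time - curve$time)) > 1e-9)
      stop("blank curve must share the sample time grid")
    y <- y - blank$absorbance
  }
  if (is.null(window)) window <- seq_len(max(5L, ceiling(0.2 * n)))
  if (length(window) < 5) stop("rate window must contain at least 5 points")
  tt <- curve$time[window]; yy <- y[window]
  fit <- stats::lm(yy ~ tt)
  # noiseless calibration curves fit exactly; the df warning is harmless
  sm <- suppressWarnings(summary(fit))
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r2 = sm$r.squared,
              se = sm$coefficients[2, 2],
              window = range(window))
  class(out) <- "rate_estimate"
  out
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate = %.4g AU/s (se %.2g, r2 %.4f, window %d..%d)\n",
              x$slope, x$se, x$r2, x$window[1], x$window[2]))
  invisible(x)
}

#' Michaelis-Menten fit
#'
#' Nonlinear least squares of v = Vmax * S / (Km + S), initialized at
#' Vmax0 = max(v) and Km0 = the substrate concentration at the first rate
#' reaching half of Vmax0. When the fitted Km falls below the smallest
#' sampled concentration, the data cannot resolve Km (the enzyme is
#' saturated at every tested S) and the fit is flagged as an
#' upper-bound regime: only \code{km_upper_bound = min(S)} is
#' interpretable.
#'
#' @param S substrate concentrations (any consistent unit).
#' @param v rates (>= 0), same length.
#' @return list of class \code{mm_fit}: \code{Km, Vmax, se_Km, se_Vmax,
#'   rss, converged, upper_bound_regime, km_upper_bound, n}.
#' @export
mm_fit <- function(S, v) {
  S <- as.numeric(S); v <- as.numeric(v)
  if (length(S) != length(v)) stop("S and v must have equal length")
  if (length(unique(S)) < 3) stop("need at least 3 distinct substrate concentrations")
  if (any(v < 0)) stop("rates must be non-negative")
  if (any(S <= 0)) stop("substrate concentrations must be positive")
  vmax0 <- max(v)
  half_idx <- which(v >= vmax0 / 2)
  km0 <- min(S[half_idx])
  dat <- data.frame(S = S, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = dat,
                      start = list(Vmax = vmax0, Km = km0),
                      lower = c(Vmax = 0, Km = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  out <- list(Km = unname(cf["Km"]), Vmax = unname(cf["Vmax"]),
              se_Km = unname(se["Km"]), se_Vmax = unname(se["Vmax"]),
              rss = sum(stats::resid(fit)^2),
              converged = fit$convInfo$isConv,
              upper_bound_regime = unname(cf["Km"]) < min(S),
              km_upper_bound = min(S),
              n = length(S))
  class(out) <- "mm_fit"
  out
}

#' @export
print.mm_fit <- function(x, ...) {
  if (x$upper_bound_regime) {
    cat(sprintf("Michaelis-Menten fit: saturated regime; Km < %.4g (smallest tested S), Vmax = %.4g (se %.2g)\n",
                x$km_upper_bound, x$Vmax, x$se_Vmax))
  } else {
    cat(sprintf("Michaelis-Menten fit: Km = %.4g (se %.2g), Vmax = %.4g (se %.2g), rss %.3g\n",
                x$Km, x$se_Km, x$Vmax, x$se_Vmax, x$rss))
  }
  invisible(x)
}

#' Relative activity normalized to a reference group
#'
#' Group means expressed as a percentage of the reference (wild-type)
#' mean; standard deviations are scaled by the same factor.
#'
#' @param groups named list of numeric rate vectors.
#' @param reference name of the reference group.
#' @return data.frame \code{label, n, mean_pct, sd_pct}.
#' @export
relative_activity <- function(groups, reference) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (!reference %in% names(groups))
    stop("reference group '", reference, "' not found")
  ref <- groups[[reference]]
  if (length(ref) == 0) stop("reference group is empty")
  ref_mean <- mean(ref)
  if (ref_mean == 0) stop("reference group mean is zero")
  rows <- lapply(names(groups), function(lb) {
    g <- groups[[lb]]
    data.frame(label = lb, n = length(g),
               mean_pct = 100 * mean(g) / ref_mean,
               sd_pct = if (length(g) > 1) 100 * stats::sd(g) / ref_mean else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' DTNB thioesterase endpoint series
#'
#' Control-subtracted thionitrobenzoate signal (A420) with a linear rate
#' estimated over the full series via the initial-rate machinery.
#'
#' @param sample data.frame \code{time, absorbance} (A420 of the stopped
#'   reaction).
#' @param control matched control on the identical time grid.
#' @return list with \code{series} (data.frame time, signal) and
#'   \code{rate} (\code{rate_estimate}).
#' @export
dtnb_endpoint <- function(sample, control) {
  stopifnot(is.data.frame(sample), is.data.frame(control))
  if (nrow(sample) != nrow(control) ||
      max(abs(sample$time - control$time)) > 1e-9)
    stop("sample and control must share an identical time grid")
  signal <- sample$absorbance - control$absorbance
  series <- data.frame(time = sample$time, signal = signal)
  rate <- initial_rate(data.frame(time = sample$time, absorbance = signal),
                       window = seq_len(nrow(sample)))
  list(series = series, rate = rate)
}

#' Read a (time, absorbance) progress-curve CSV
#'
#' Expected columns: \code{time, absorbance} and optionally \code{label};
#' with a label column a named list of curves is returned.
#'
#' @param path CSV path.
#' @param wavelength nm metadata attached to each curve.
#' @return a \code{progress_curve}, or a named list of them.
#' @export
read_progress_csv <- function(path, wavelength = NA_real_) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "absorbance") %in% names(d)))
    stop("CSV must have columns time, absorbance")
  if ("label" %in% names(d)) {
    lapply(split(d, d$label), function(g)
      progress_curve(g$time, g$absorbance, wavelength, g$label[1]))
  } else {
    progress_curve(d$time, d$absorbance, wavelength)
  }
}

#' Read a (substrate, rate) table CSV
#'
#' Expected columns: \code{S} (concentration) and \code{v} (rate).
#'
#' @param path CSV path.
#' @return data.frame \code{S, v}.
#' @export
read_rate_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("S", "v") %in% names(d)))
    stop("CSV must have columns S, v")
  d[, c("S", "v")]
}
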