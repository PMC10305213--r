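#' Lognormal particle-size distribution
#'
#' Constructs the two-parameter lognormal size distribution that underlies
#' every diameter metric in aerosol characterization: the geometric diameter
#' `Dg` (microscopy counts), the volume diameter `Dv` (laser diffraction) and
#' the mass median aerodynamic diameter `MMAD` (cascade impaction) are all
#' medians of such a distribution, each paired with a geometric standard
#' deviation (GSD).
#'
#' @param median_um median diameter in micrometres (the 50th-percentile
#'   diameter). Must be positive. All diameters in this package are in
#'   micrometres; no unit inference is performed.
#' @param gsd geometric standard deviation, dimensionless, `>= 1`.
#'   `gsd == 1` is the degenerate monodisperse limit: cumulative queries
#'   become a step function at the median.
#' @param label free-text name for which diameter this distribution
#'   describes, e.g. `"Dg"`, `"Dv"` or `"MMAD"`.
#'
#' @return An object of class `lognormal_psd` with fields `median_um`,
#'   `gsd` and `label`.
#' @examples
#' psd <- lognormal_psd(2.70, 1.54, label = "Dg")
#' fraction_below(psd, 2.70)       # 0.5 by definition
#' band_fraction(psd, 5, 7)        # respirable-band arithmetic
#' @export
lognormal_psd <- function(median_um, gsd, label = "") {
  stopifnot(is.numeric(median_um), length(median_um) == 1L,
            is.numeric(gsd), length(gsd) == 1L)
  if (!is.finite(median_um) || median_um <= 0)
    stop_invalid("`median_um` must be a positive finite diameter in um, got ",
                 format(median_um))
  if (!is.finite(gsd) || gsd < 1)
    stop_invalid("`gsd` must be finite and >= 1, got ", format(gsd))
  structure(
    list(median_um = as.numeric(median_um), gsd = as.numeric(gsd),
         label = as.character(label)),
    class = "lognormal_psd"
  )
}

#' @export
print.lognormal_psd <- function(x, ...) {
  lab <- if (nzchar(x$label)) paste0(" [", x$label, "]") else ""
  cat(sprintf("Lognormal PSD%s: median %.4g um, GSD %.4g\n",
              lab, x$median_um, x$gsd))
  invisible(x)
}

#' Geometric standard deviation from the 84th and 16th percentile diameters
#'
#' The GSD of a lognormal size distribution is `sqrt(d84 / d16)`, the ratio
#' of the diameters one geometric standard deviation above and below the
#' median.
#'
#' @param d84 diameter (um) at the 84th cumulative percentile.
#' @param d16 diameter (um) at the 16th cumulative percentile.
#' @return The dimensionless GSD (`>= 1`).
#' @examples
#' gsd_from_quantiles(4.0, 1.0)  # 2
#' @export
gsd_from_quantiles <- function(d84, d16) {
  stopifnot(is.numeric(d84), is.numeric(d16))
  if (any(!is.finite(d84)) || any(!is.finite(d16)) ||
      any(d16 <= 0) || any(d84 <= 0))
    stop_invalid("quantile diameters must be positive and finite")
  if (any(d84 < d16))
    stop_invalid("`d84` must be >= `d16` (inverted quantiles)")
  sqrt(d84 / d16)
}

#' Quantile (inverse CDF) of a lognormal PSD
#'
#' Returns the diameter below which a fraction `probs` of the distribution
#' lies: `median_um * gsd^z(p)` with `z` the standard-normal quantile.
#'
#' @param x a [lognormal_psd()].
#' @param probs probabilities strictly inside (0, 1).
#' @param ... ignored.
#' @return Diameters in um, same length as `probs`.
#' @examples
#' quantile(lognormal_psd(2.70, 1.54), c(0.1587, 0.5, 0.8413))
#' @export
quantile.lognormal_psd <- function(x, probs = c(0.16, 0.5, 0.84), ...) {
  stopifnot(is.numeric(probs))
  if (any(!is.finite(probs)) || any(probs <= 0) || any(probs >= 1))
    stop_invalid("`probs` must lie strictly inside (0, 1)")
  x$median_um * x$gsd^stats::qnorm(probs)
}

#' Cumulative fraction of a PSD below a diameter
#'
#' The lognormal CDF `Phi(ln(d / median) / ln(gsd))`. For the degenerate
#' `gsd == 1` case this is a step function: 0 below the median, 1 at or
#' above it (boundary mass belongs to the upper side).
#'
#' @param psd a [lognormal_psd()].
#' @param d diameters in um, `> 0` (0 and `Inf` are accepted as band edges
#'   and map to 0 and 1).
#' @return Fractions in `[0, 1]`, same length as `d`.
#' @examples
#' fraction_below(lognormal_psd(2.30, 1.65), 1.0)
#' @export
fraction_below <- function(psd, d) {
  stopifnot(inherits(psd, "lognormal_psd"), is.numeric(d))
  if (any(is.na(d)) || any(d < 0))
    stop_invalid("diameters must be positive (0/Inf allowed as band edges)")
  out <- numeric(length(d))
  zero <- d == 0
  inf <- is.infinite(d)
  mid <- !zero & !inf
  if (psd$gsd == 1) {
    out[mid] <- as.numeric(d[mid] >= psd$median_um)
  } else {
    out[mid] <- stats::pnorm(log(d[mid] / psd$median_um) / log(psd$gsd))
  }
  out[inf] <- 1
  out
}

#' Fraction of a PSD inside a diameter band
#'
#' Mass (or count) fraction between two diameters, the quantity behind the
#' regional airway-deposition tables: e.g. the human bronchial band is
#' 5--7 um. `lo = 0` means an open lower bound, `hi = Inf` an open upper
#' bound; bands that partition `(0, Inf)` sum to 1.
#'
#' @param psd a [lognormal_psd()].
#' @param lo,hi band bounds in um with `0 <= lo < hi`.
#' @return Fraction in `[0, 1]`.
#' @examples
#' band_fraction(lognormal_psd(2.70, 1.54), 5, 7) * 100   # ~6.3 %
#' @export
band_fraction <- function(psd, lo, hi) {
  stopifnot(inherits(psd, "lognormal_psd"),
            is.numeric(lo), length(lo) == 1L,
            is.numeric(hi), length(hi) == 1L)
  if (is.na(lo) || is.na(hi) || lo < 0 || lo >= hi)
    stop_invalid("band bounds must satisfy 0 <= lo < hi, got [",
                 format(lo), ", ", format(hi), "]")
  if (psd$gsd == 1) {
    # point mass at the median; boundary mass belongs to the upper band
    return(as.numeric(lo <= psd$median_um && psd$median_um < hi))
  }
  fraction_below(psd, hi) - fraction_below(psd, lo)
}

#' Cumulative particle-sizing data
#'
#' A validated table of (diameter, cumulative fraction undersize) points,
#' the digital equivalent of a cumulative size plot on log-probability
#' paper. Small monotonicity violations (absolute decreases up to
#' `tol_monotone`, typical of digitization noise) are repaired by isotonic
#' averaging; larger violations indicate corrupt data and are an error.
#'
#' @param diameter_um strictly increasing positive diameters (um).
#' @param fraction_undersize cumulative fractions strictly inside (0, 1).
#' @param source free text describing the measurement (image counts, laser
#'   diffraction, impactor).
#' @param tol_monotone maximum absolute decrease repaired silently
#'   (default 0.005).
#' @return An object of class `cumulative_size_data`.
#' @export
cumulative_size_data <- function(diameter_um, fraction_undersize,
                                 source = "", tol_monotone = 0.005) {
  stopifnot(is.numeric(diameter_um), is.numeric(fraction_undersize),
            length(diameter_um) == length(fraction_undersize))
  if (any(!is.finite(diameter_um)) || any(diameter_um <= 0))
    stop_invalid("diameters must be positive and finite")
  if (is.unsorted(diameter_um, strictly = TRUE))
    stop_invalid("diameters must be strictly increasing")
  if (any(!is.finite(fraction_undersize)) ||
      any(fraction_undersize <= 0) || any(fraction_undersize >= 1))
    stop_invalid("cumulative fractions must lie strictly inside (0, 1); ",
                 "drop 0%/100% rows before construction")
  viol <- diff(fraction_undersize)
  if (any(viol < -tol_monotone))
    stop_invalid("cumulative fractions decrease by more than ",
                 format(tol_monotone), " (non-monotone beyond tolerance)")
  if (any(viol < 0)) {
    # pool-adjacent-violators repair of digitization noise
    fraction_undersize <- stats::isoreg(log(diameter_um),
                                        fraction_undersize)$yf
    fraction_undersize <- pmin(pmax(fraction_undersize, 1e-12), 1 - 1e-12)
  }
  structure(
    list(points = data.frame(diameter_um = as.numeric(diameter_um),
                             fraction_undersize = as.numeric(fraction_undersize)),
         source = as.character(source)),
    class = "cumulative_size_data"
  )
}

#' @export
print.cumulative_size_data <- function(x, ...) {
  cat(sprintf("Cumulative size data (%d points%s)\n", nrow(x$points),
              if (nzchar(x$source)) paste0(", ", x$source) else ""))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Fit a lognormal PSD to cumulative sizing data
#'
#' Formalizes the log-probability-paper procedure: ordinary least squares of
#' the probit of the cumulative fraction against the natural log of the
#' diameter, using all usable points. The fitted line gives
#' `median = exp(-intercept/slope)` and `gsd = exp(1/slope)`; the slope must
#' be positive (a proper, non-degenerate distribution).
#'
#' @param data a [cumulative_size_data()] object.
#' @return An object of class `psd_fit`: the fitted [lognormal_psd()]
#'   (`$psd`), residuals on the probit scale (`$residuals`), `$r_squared`,
#'   and `$n_used`.
#' @examples
#' psd <- lognormal_psd(2.3, 1.65)
#' p <- c(0.1, 0.3, 0.5, 0.7, 0.9)
#' dat <- cumulative_size_data(quantile(psd, p), p)
#' fit_lognormal(dat)$psd
#' @export
fit_lognormal <- function(data) {
  stopifnot(inherits(data, "cumulative_size_data"))
  pts <- data$points
  if (nrow(pts) < 2L)
    stop_compute("need at least 2 usable points to fit, got ", nrow(pts))
  if (length(unique(pts$diameter_um)) < 2L)
    stop_compute("all points share one diameter; fit is degenerate")
  z <- stats::qnorm(pts$fraction_undersize)
  x <- log(pts$diameter_um)
  fit <- stats::lm(z ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (!is.finite(slope) || slope <= 0)
    stop_compute("probit-vs-log slope is not positive (", format(slope),
                 "); data are not consistent with a lognormal distribution")
  psd <- lognormal_psd(exp(-intercept / slope), exp(1 / slope),
                       label = data$source)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((z - mean(z))^2)
  structure(
    list(psd = psd,
         residuals = unname(stats::residuals(fit)),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         n_used = nrow(pts),
         slope = slope, intercept = intercept),
    class = "psd_fit"
  )
}

#' @export
print.psd_fit <- function(x, ...) {
  print(x$psd)
  cat(sprintf("  probit-vs-log fit: %d points, R^2 = %.5f\n",
              x$n_used, x$r_squared))
  invisible(x)
}
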