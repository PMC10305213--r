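#' Airway region scheme for one species and administration mode
#'
#' An ordered, contiguous, non-overlapping set of diameter bands, each
#' mapped to an anatomical airway region (Weibel-generation annotation
#' carried as text). Regional deposition prediction here is pure size-band
#' assignment: the fraction of the size distribution inside a region's band
#' is the fraction of the dose predicted to deposit there. Mass above the
#' last closed band is reported as residual (extrathoracic / not
#' deposited). An optional inhalability cutoff records the nasal filtration
#' diameter of obligate nose breathers such as the rat (~3 um); it must
#' coincide with a band boundary.
#'
#' @param species free text, e.g. `"human"` or `"rat"`.
#' @param mode `"passive"` (inhaled) or `"direct"` (intratracheal
#'   administration).
#' @param regions `data.frame` with columns `name`, `lo_um`, `hi_um`
#'   (`Inf` allowed for the last band), `generations` (text annotation).
#' @param inhalability_cutoff_um optional nasal cutoff diameter (um).
#' @return Object of class `region_scheme`.
#' @seealso [builtin_scheme()], [predict_regions()].
#' @export
region_scheme <- function(species, mode, regions,
                          inhalability_cutoff_um = NULL) {
  need <- c("name", "lo_um", "hi_um")
  if (!all(need %in% names(regions)))
    stop_invalid("`regions` must have columns ", paste(need, collapse = ", "))
  if (!"generations" %in% names(regions)) regions$generations <- ""
  regions <- regions[, c("name", "lo_um", "hi_um", "generations")]
  if (nrow(regions) < 1L) stop_invalid("at least one region required")
  if (any(regions$lo_um < 0) || any(regions$lo_um >= regions$hi_um))
    stop_invalid("each region needs 0 <= lo_um < hi_um")
  o <- order(regions$lo_um)
  regions <- regions[o, , drop = FALSE]
  if (nrow(regions) > 1L &&
      any(abs(regions$lo_um[-1L] - regions$hi_um[-nrow(regions)]) > 1e-9))
    stop_invalid("region bands must be contiguous and non-overlapping")
  if (!is.null(inhalability_cutoff_um)) {
    bounds <- unique(c(regions$lo_um, regions$hi_um))
    if (!any(abs(bounds - inhalability_cutoff_um) < 1e-9))
      stop_invalid("`inhalability_cutoff_um` must coincide with a band boundary")
  }
  structure(
    list(species = as.character(species), mode = as.character(mode),
         regions = regions,
         inhalability_cutoff_um = inhalability_cutoff_um),
    class = "region_scheme"
  )
}

#' @export
print.region_scheme <- function(x, ...) {
  cat(sprintf("Region scheme: %s, %s inhalation\n", x$species, x$mode))
  print(x$regions, row.names = FALSE)
  if (!is.null(x$inhalability_cutoff_um))
    cat(sprintf("  inhalability cutoff (nose): %g um\n",
                x$inhalability_cutoff_um))
  invisible(x)
}

#' Built-in airway region schemes
#'
#' Ships the two passive-inhalation schemes used throughout the package:
#'
#' * `human`: alveoli < 2 um (Weibel generations 17--23), bronchioles
#'   2--5 um (gen. 5--17), bronchi 5--7 um (gen. 1--4), trachea 7--10 um
#'   (gen. 0); mass above 10 um is residual (extrathoracic / not
#'   deposited).
#' * `rat`: alveoli < 1 um, bronchioles 1--2 um, bronchi 2--3 um, trachea
#'   > 3 um (open band), with a 3 um nasal inhalability cutoff — rats are
#'   obligate nose breathers, and particles above ~3 um are filtered by the
#'   nose before reaching the airways.
#'
#' @param species `"human"` or `"rat"`.
#' @param mode only `"passive"` is supported.
#' @return A [region_scheme()].
#' @export
builtin_scheme <- function(species = c("human", "rat"), mode = "passive") {
  if (length(species) != 1L || !species %in% c("human", "rat") ||
      mode != "passive")
    stop_invalid("unsupported scheme; supported: (human, passive), ",
                 "(rat, passive)")
  if (species == "human") {
    region_scheme("human", "passive", data.frame(
      name = c("alveoli", "bronchioles", "bronchi", "trachea"),
      lo_um = c(0, 2, 5, 7), hi_um = c(2, 5, 7, 10),
      generations = c("17-23", "5-17", "1-4", "0")))
  } else {
    region_scheme("rat", "passive", data.frame(
      name = c("alveoli", "bronchioles", "bronchi", "trachea"),
      lo_um = c(0, 1, 2, 3), hi_um = c(1, 2, 3, Inf),
      generations = c("17-23", "5-17", "1-4", "0")),
      inhalability_cutoff_um = 3)
  }
}

#' Predict regional deposition fractions from a size distribution
#'
#' Maps a lognormal size distribution onto a region scheme: each region
#' receives `100 * band_fraction(psd, lo, hi)` percent of the dose;
#' whatever falls outside every band is the residual. Percentages plus
#' residual sum to 100 exactly. When the scheme carries an inhalability
#' cutoff, the mass above it is additionally reported as
#' `not_inhaled_percent`; with `nose_mode = "annotate"` (default) the band
#' assignment itself is unchanged (the open top band keeps its anatomical
#' label), while `nose_mode = "strict"` truncates every band at the cutoff
#' and moves the above-cutoff mass into the residual as nasally filtered.
#'
#' @param psd a [lognormal_psd()].
#' @param scheme a [region_scheme()].
#' @param nose_mode `"annotate"` or `"strict"`; only relevant when the
#'   scheme has an inhalability cutoff.
#' @return Object of class `deposition_prediction`: `fractions_percent`
#'   (named by region), `residual_percent`, `not_inhaled_percent` (or
#'   `NA`), and `basis` (the PSD used).
#' @examples
#' predict_regions(lognormal_psd(2.70, 1.54, "Dg"), builtin_scheme("human"))
#' @export
predict_regions <- function(psd, scheme, nose_mode = c("annotate", "strict")) {
  stopifnot(inherits(psd, "lognormal_psd"), inherits(scheme, "region_scheme"))
  nose_mode <- match.arg(nose_mode)
  reg <- scheme$regions
  cut <- scheme$inhalability_cutoff_um
  strict <- nose_mode == "strict" && !is.null(cut)
  frac <- vapply(seq_len(nrow(reg)), function(i) {
    lo <- reg$lo_um[i]; hi <- reg$hi_um[i]
    if (strict) {
      hi <- min(hi, cut)
      if (lo >= hi) return(0)
    }
    band_fraction(psd, lo, hi)
  }, numeric(1))
  names(frac) <- reg$name
  pct <- 100 * frac
  residual <- 100 - sum(pct)
  not_inhaled <- if (!is.null(cut)) 100 * (1 - fraction_below(psd, cut))
                 else NA_real_
  structure(
    list(fractions_percent = pct,
         residual_percent = residual,
         not_inhaled_percent = not_inhaled,
         nose_mode = if (is.null(cut)) NA_character_ else nose_mode,
         basis = psd, scheme = scheme),
    class = "deposition_prediction"
  )
}

#' @export
print.deposition_prediction <- function(x, ...) {
  lab <- if (nzchar(x$basis$label)) x$basis$label else "PSD"
  cat(sprintf("Deposition prediction (%s: median %.4g um, GSD %.4g) on %s/%s\n",
              lab, x$basis$median_um, x$basis$gsd,
              x$scheme$species, x$scheme$mode))
  df <- data.frame(region = names(x$fractions_percent),
                   percent = round(x$fractions_percent, 2))
  print(df, row.names = FALSE)
  cat(sprintf("  residual (outside bands): %.2f%%\n", x$residual_percent))
  if (!is.na(x$not_inhaled_percent))
    cat(sprintf("  above nasal cutoff (not inhaled): %.2f%% [%s mode]\n",
                x$not_inhaled_percent, x$nose_mode))
  invisible(x)
}

#' Compare deposition predictions across diameter bases
#'
#' The same aerosol characterized by geometric diameter (Dg), volume
#' diameter (Dv) or MMAD can yield very different predicted deposition
#' patterns; choosing the wrong basis is a classic design error. This
#' tabulates one prediction per provided basis on a common scheme and
#' raises a structured warning when any region differs by more than
#' `warn_gap` percentage points between bases.
#'
#' @param scheme a [region_scheme()].
#' @param dg,dv,mmad optional [lognormal_psd()] objects; at least one
#'   required.
#' @param warn_gap disagreement threshold in percentage points
#'   (default 20).
#' @param nose_mode passed to [predict_regions()].
#' @return `data.frame` with one row per basis (columns: `basis`, one per
#'   region, `residual`); attribute `"predictions"` holds the full
#'   objects.
#' @export
compare_bases <- function(scheme, dg = NULL, dv = NULL, mmad = NULL,
                          warn_gap = 20, nose_mode = "annotate") {
  bases <- list(Dg = dg, Dv = dv, MMAD = mmad)
  bases <- bases[!vapply(bases, is.null, logical(1))]
  if (length(bases) == 0L)
    stop_invalid("at least one basis (dg, dv or mmad) must be provided")
  preds <- lapply(bases, predict_regions, scheme = scheme,
                  nose_mode = nose_mode)
  mat <- t(vapply(preds, function(p) p$fractions_percent,
                  numeric(nrow(scheme$regions))))
  out <- data.frame(basis = names(bases), mat,
                    residual = vapply(preds, `[[`, numeric(1),
                                      "residual_percent"),
                    row.names = NULL, check.names = FALSE)
  if (nrow(mat) > 1L) {
    gap <- apply(mat, 2, function(col) diff(range(col)))
    if (any(gap > warn_gap))
      warn_flag("diameter bases disagree by more than ", warn_gap,
                " percentage points in region(s): ",
                paste(colnames(mat)[gap > warn_gap], collapse = ", "),
                class = "aeroperf_basis_disagreement")
  }
  attr(out, "predictions") <- preds
  out
}
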