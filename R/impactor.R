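#' Cascade-impactor device definition
#'
#' Describes a next-generation impactor (NGI): seven stages with strictly
#' decreasing D50 cutoff diameters at a reference flow, plus a micro-orifice
#' collector (MOC) that is treated as collecting everything below the
#' stage-7 cutoff. Cutoffs at other flows follow the usual power-law
#' scaling `cutoff(Q) = cutoff_ref * (Q_ref / Q)^exponent` per stage.
#'
#' @param name device/calibration name.
#' @param ref_flow_lpm reference volumetric flow (L/min) of the calibration.
#' @param cutoff_um_at_ref length-7 vector of stage D50 cutoffs (um) at the
#'   reference flow, strictly decreasing from stage 1 to stage 7.
#' @param scaling_exponent per-stage flow-scaling power; recycled to
#'   length 7 (default 0.5 for all stages).
#' @param flow_range_lpm validity range `c(min, max)` of the scaling.
#' @return An object of class `impactor_device`.
#' @seealso [ngi_device()] for the shipped default calibration,
#'   [stage_cutoffs()].
#' @export
impactor_device <- function(name, ref_flow_lpm, cutoff_um_at_ref,
                            scaling_exponent = 0.5,
                            flow_range_lpm = c(10, 100)) {
  stopifnot(is.numeric(ref_flow_lpm), ref_flow_lpm > 0,
            is.numeric(cutoff_um_at_ref))
  if (length(cutoff_um_at_ref) != 7L)
    stop_invalid("an NGI definition needs 7 stage cutoffs, got ",
                 length(cutoff_um_at_ref))
  if (any(cutoff_um_at_ref <= 0) || any(diff(cutoff_um_at_ref) >= 0))
    stop_invalid("stage cutoffs must be positive and strictly decreasing")
  scaling_exponent <- rep_len(scaling_exponent, 7L)
  stopifnot(length(flow_range_lpm) == 2L, flow_range_lpm[1] < flow_range_lpm[2])
  structure(
    list(name = as.character(name),
         ref_flow_lpm = as.numeric(ref_flow_lpm),
         stages = data.frame(stage = 1:7,
                             cutoff_um_at_ref = as.numeric(cutoff_um_at_ref),
                             scaling_exponent = as.numeric(scaling_exponent)),
         flow_range_lpm = as.numeric(flow_range_lpm)),
    class = "impactor_device"
  )
}

#' Default NGI calibration
#'
#' The widely used NGI archival stage cutoffs at 60 L/min
#' (8.06, 4.46, 2.82, 1.66, 0.94, 0.55, 0.34 um) with square-root flow
#' scaling, valid 10--100 L/min. Note that the human fine-particle cutoff
#' convention (4.46 um, stages 3--7 + MOC) coincides with the stage-2
#' cutoff of this calibration.
#'
#' @return An `impactor_device`.
#' @export
ngi_device <- function() {
  impactor_device("NGI (archival calibration, 60 L/min reference)",
                  ref_flow_lpm = 60,
                  cutoff_um_at_ref = c(8.06, 4.46, 2.82, 1.66, 0.94, 0.55, 0.34),
                  scaling_exponent = 0.5,
                  flow_range_lpm = c(10, 100))
}

#' @export
print.impactor_device <- function(x, ...) {
  cat(sprintf("Impactor device: %s\n  reference flow %g L/min, valid %g-%g L/min\n",
              x$name, x$ref_flow_lpm, x$flow_range_lpm[1], x$flow_range_lpm[2]))
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Stage cutoff diameters at an operating flow
#'
#' Scales each stage's reference-flow D50 cutoff to the operating flow with
#' its per-stage power law, or returns a user-supplied explicit cutoff table
#' unchanged (explicit calibrations override scaling).
#'
#' @param device an [impactor_device()].
#' @param flow_lpm operating flow (L/min), inside the device's validity
#'   range.
#' @param override optional length-7 vector of explicit cutoffs (um) for
#'   this flow; bypasses the scaling law.
#' @return Length-7 numeric vector of strictly decreasing cutoffs (um).
#' @examples
#' stage_cutoffs(ngi_device(), 60)   # the reference cutoffs themselves
#' stage_cutoffs(ngi_device(), 15)   # sqrt-law scaled
#' @export
stage_cutoffs <- function(device, flow_lpm, override = NULL) {
  stopifnot(inherits(device, "impactor_device"),
            is.numeric(flow_lpm), length(flow_lpm) == 1L)
  if (!is.null(override)) {
    if (length(override) != 7L || any(override <= 0))
      stop_invalid("`override` must be 7 positive cutoffs")
    cut <- as.numeric(override)
  } else {
    if (flow_lpm < device$flow_range_lpm[1] || flow_lpm > device$flow_range_lpm[2])
      stop_invalid("flow ", format(flow_lpm), " L/min outside the device's ",
                   "validity range [", device$flow_range_lpm[1], ", ",
                   device$flow_range_lpm[2], "] L/min")
    cut <- device$stages$cutoff_um_at_ref *
      (device$ref_flow_lpm / flow_lpm)^device$stages$scaling_exponent
  }
  if (any(diff(cut) >= 0))
    stop_invalid("resulting stage cutoffs are not strictly decreasing")
  cut
}

#' One cascade-impaction experiment
#'
#' Holds the raw gravimetric/assay record of a single impactor run: the mass
#' loaded into the device, and the masses recovered from the induction port,
#' each of the seven stages, and the MOC. Mass units are arbitrary but must
#' be consistent within the run.
#'
#' @param device free-text device name (HandiHaler, Plastiape, Insufflator,
#'   MicroSprayer, nebulizer, ...).
#' @param flow_lpm volumetric flow (L/min) the run was sampled at.
#' @param loaded_mass mass loaded into the device, `> 0` for emitted-dose
#'   computation.
#' @param induction_port_mass mass recovered from the induction port.
#' @param stage_masses length-7 vector of stage masses (stage 1 first).
#' @param moc_mass mass on the micro-orifice collector.
#' @param duration_s sampling time in seconds (metadata).
#' @return An object of class `impactor_run`.
#' @export
impactor_run <- function(device = "", flow_lpm, loaded_mass,
                         induction_port_mass, stage_masses, moc_mass,
                         duration_s = 60) {
  stopifnot(is.numeric(flow_lpm), length(flow_lpm) == 1L)
  if (!is.finite(flow_lpm) || flow_lpm <= 0)
    stop_invalid("`flow_lpm` must be positive")
  if (length(stage_masses) != 7L)
    stop_invalid("`stage_masses` must have 7 entries (stages 1-7), got ",
                 length(stage_masses))
  m <- c(loaded_mass, induction_port_mass, stage_masses, moc_mass)
  if (any(!is.finite(m)) || any(m < 0))
    stop_invalid("all masses must be finite and non-negative")
  structure(
    list(device = as.character(device), flow_lpm = as.numeric(flow_lpm),
         duration_s = as.numeric(duration_s),
         loaded_mass = as.numeric(loaded_mass),
         induction_port_mass = as.numeric(induction_port_mass),
         stage_masses = as.numeric(stage_masses),
         moc_mass = as.numeric(moc_mass)),
    class = "impactor_run"
  )
}

#' @export
print.impactor_run <- function(x, ...) {
  cat(sprintf("Impactor run: %s at %g L/min, loaded %g\n",
              if (nzchar(x$device)) x$device else "(unnamed device)",
              x$flow_lpm, x$loaded_mass))
  cat("  port", format(x$induction_port_mass), "| stages",
      paste(format(x$stage_masses), collapse = " "),
      "| MOC", format(x$moc_mass), "\n")
  invisible(x)
}

# total mass used for sizing (stages + MOC; excludes the induction port)
sizing_mass <- function(run) sum(run$stage_masses) + run$moc_mass

# total mass recovered anywhere in the impactor
recovered_mass <- function(run) run$induction_port_mass + sizing_mass(run)

#' Cumulative mass fraction undersize at each stage cutoff
#'
#' For each stage cutoff `c_i`, the fraction of the sizing mass
#' (stages + MOC) collected on surfaces with cutoffs smaller than `c_i`,
#' i.e. the mass aerodynamically finer than `c_i`. The induction port is
#' excluded from this normalization (sizing is over the classified mass
#' only).
#'
#' @param run an [impactor_run()].
#' @param cutoffs length-7 decreasing stage cutoffs (um), from
#'   [stage_cutoffs()].
#' @return `data.frame` with columns `cutoff_um` and `fraction` (cumulative
#'   fraction undersize), stage 1 first.
#' @export
cumulative_undersize <- function(run, cutoffs) {
  stopifnot(inherits(run, "impactor_run"), length(cutoffs) == 7L)
  tot <- sizing_mass(run)
  if (tot <= 0)
    stop_compute("all sizing masses (stages + MOC) are zero; nothing to size")
  below <- rev(cumsum(rev(c(run$stage_masses[-1L], run$moc_mass))))
  data.frame(cutoff_um = as.numeric(cutoffs), fraction = below / tot)
}

# Interpolate the diameter at cumulative fraction p on the probit-vs-ln
# scale using the two bracketing stage cutoffs (USP-style reduction).
# Returns list(value, flag) where flag is "" | "out_of_range" |
# "extrapolated"; ties (fraction exactly p at a cutoff) return that cutoff.
interp_quantile_probit <- function(curve, p, extrapolate = FALSE) {
  hit <- which(curve$fraction == p)
  if (length(hit) > 0L)
    return(list(value = curve$cutoff_um[hit[1L]], flag = ""))
  usable <- curve$fraction > 0 & curve$fraction < 1
  cv <- curve[usable, , drop = FALSE]
  if (nrow(cv) < 2L || p <= 0 || p >= 1)
    return(list(value = NA_real_, flag = "out_of_range"))
  # order by increasing cutoff (fraction increases with cutoff)
  cv <- cv[order(cv$cutoff_um), , drop = FALSE]
  z <- stats::qnorm(cv$fraction)
  x <- log(cv$cutoff_um)
  zp <- stats::qnorm(p)
  line_at <- function(i, j)
    exp(x[i] + (zp - z[i]) * (x[j] - x[i]) / (z[j] - z[i]))
  n <- nrow(cv)
  if (zp < z[1L] || zp > z[n]) {
    if (!extrapolate)
      return(list(value = NA_real_, flag = "out_of_range"))
    idx <- if (zp < z[1L]) c(1L, 2L) else c(n - 1L, n)
    return(list(value = line_at(idx[1L], idx[2L]), flag = "extrapolated"))
  }
  i <- max(which(z <= zp))
  list(value = line_at(i, i + 1L), flag = "")
}

#' Mass median aerodynamic diameter of an impactor run
#'
#' USP-style reduction: the cumulative-undersize curve is interpolated on
#' the probit (standard-normal quantile) vs log-diameter scale between the
#' two stage cutoffs bracketing 50% to give the MMAD; the 84.13% and 15.87%
#' diameters obtained the same way give the GSD via
#' [gsd_from_quantiles()]. Quantiles falling outside the stage cutoff range
#' are reported as `NA` with an `"out_of_range"` flag and the bounding
#' cutoff, unless `extrapolate = TRUE`, in which case the probit line
#' through the two nearest stages is extended and the result flagged
#' `"extrapolated"` (an explicit, visible choice, never silent).
#'
#' @param run an [impactor_run()].
#' @param cutoffs length-7 decreasing stage cutoffs (um).
#' @param extrapolate allow flagged extrapolation beyond the cutoff range.
#' @return A list with `mmad_um`, `gsd`, `d84_um`, `d16_um`, a character
#'   vector `flags`, `bounds` (range of stage cutoffs), and the
#'   cumulative `curve`.
#' @examples
#' run <- simulate_impactor_run(lognormal_psd(3, 1.8), ngi_device(), 60,
#'                              loaded_mass = 10, ed_true = 0.8,
#'                              port_fraction = 0.2, seed = 1)
#' mmad(run, stage_cutoffs(ngi_device(), 60))$mmad_um
#' @export
mmad <- function(run, cutoffs, extrapolate = FALSE) {
  curve <- cumulative_undersize(run, cutoffs)
  if (any(diff(curve$fraction) > 1e-9))
    stop_compute("cumulative curve is not monotone")  # cannot occur for valid runs
  flags <- character(0)
  q50 <- interp_quantile_probit(curve, 0.5, extrapolate)
  p84 <- stats::pnorm(1); p16 <- stats::pnorm(-1)
  q84 <- interp_quantile_probit(curve, p84, extrapolate)
  q16 <- interp_quantile_probit(curve, p16, extrapolate)
  if (nzchar(q50$flag)) flags <- c(flags, paste0("mmad_", q50$flag))
  if (nzchar(q84$flag) || nzchar(q16$flag))
    flags <- c(flags, paste0("gsd_", unique(c(q84$flag, q16$flag)[
      nzchar(c(q84$flag, q16$flag))])))
  gsd <- if (is.na(q84$value) || is.na(q16$value)) NA_real_ else
    gsd_from_quantiles(q84$value, q16$value)
  list(mmad_um = q50$value, gsd = gsd,
       d84_um = q84$value, d16_um = q16$value,
       flags = flags, bounds = range(cutoffs), curve = curve)
}

#' Emitted dose of an impactor run
#'
#' Percentage of the loaded mass recovered anywhere in the impactor
#' (induction port + stages + MOC). Recovery above 100% is reported with an
#' over-recovery flag rather than clamped.
#'
#' @param run an [impactor_run()].
#' @return List with `ed_percent` and logical `over_recovery`.
#' @examples
#' run <- impactor_run("MicroSprayer", 28.3, loaded_mass = 10,
#'                     induction_port_mass = 6, stage_masses = rep(0.0995, 7),
#'                     moc_mass = 0.0005)
#' emitted_dose(run)$ed_percent  # 66.97
#' @export
emitted_dose <- function(run) {
  stopifnot(inherits(run, "impactor_run"))
  if (run$loaded_mass <= 0)
    stop_invalid("`loaded_mass` must be positive to compute emitted dose")
  ed <- 100 * recovered_mass(run) / run$loaded_mass
  list(ed_percent = ed, over_recovery = ed > 100)
}

# stage groups behind the conventional species FPF cutoffs
fpf_stage_groups <- list(
  human  = list(stages = 3:7, cutoff_um = 4.46),
  rodent = list(stages = 4:7, cutoff_um = 2.28)
)

#' Fine particle fraction by conventional stage grouping
#'
#' FPF as the percentage of recovered mass on the stage group below the
#' species' conventional cutoff diameter: for humans, 4.46 um (stages 3--7
#' plus MOC); for small rodents (rats, guinea pigs), 2.28 um (stages 4--7
#' plus MOC). The denominator is the total mass recovered from the impactor
#' and by default includes the induction port; set `include_port = FALSE`
#' to normalize over the classified (stages + MOC) mass only.
#'
#' @param run an [impactor_run()].
#' @param species `"human"` or `"rodent"`.
#' @param include_port include induction-port mass in the denominator
#'   (default `TRUE`).
#' @return FPF in percent.
#' @export
fpf_by_stage_group <- function(run, species = c("human", "rodent"),
                               include_port = TRUE) {
  stopifnot(inherits(run, "impactor_run"))
  if (length(species) == 1L && !species %in% names(fpf_stage_groups))
    stop_invalid("unknown species '", species, "'; configured species: ",
                 paste(names(fpf_stage_groups), collapse = ", "))
  species <- match.arg(species)
  denom <- if (include_port) recovered_mass(run) else sizing_mass(run)
  if (denom <= 0)
    stop_compute("no mass recovered; FPF undefined")
  grp <- fpf_stage_groups[[species]]
  100 * (sum(run$stage_masses[grp$stages]) + run$moc_mass) / denom
}

#' Fine particle fraction at an exact cutoff by interpolation
#'
#' Alternative to the stage-group convention for runs whose stage cutoffs at
#' the operating flow do not equal the species cutoff: the cumulative
#' undersize fraction at `cutoff_um` is obtained by probit/log
#' interpolation on the stage curve and renormalized to the same
#' denominator as [fpf_by_stage_group()]. Cutoffs outside the stage range
#' are clamped to the nearest stage's cumulative value and flagged.
#'
#' @param run an [impactor_run()].
#' @param cutoffs length-7 decreasing stage cutoffs (um).
#' @param cutoff_um the aerodynamic cutoff diameter (um).
#' @param include_port include induction-port mass in the denominator.
#' @return List with `fpf_percent` and `flags`.
#' @export
fpf_interpolated <- function(run, cutoffs, cutoff_um, include_port = TRUE) {
  stopifnot(is.numeric(cutoff_um), length(cutoff_um) == 1L, cutoff_um > 0)
  curve <- cumulative_undersize(run, cutoffs)
  flags <- character(0)
  hit <- which(curve$cutoff_um == cutoff_um)
  if (length(hit) > 0L) {
    frac <- curve$fraction[hit[1L]]
  } else {
    usable <- curve[curve$fraction > 0 & curve$fraction < 1, , drop = FALSE]
    if (nrow(usable) < 2L) {
      # degenerate curve (all 0/1): step lookup
      frac <- if (cutoff_um >= max(curve$cutoff_um)) max(curve$fraction)
              else min(curve$fraction[curve$cutoff_um >= cutoff_um], 1)
      flags <- c(flags, "degenerate_curve")
    } else if (cutoff_um < min(usable$cutoff_um) ||
               cutoff_um > max(usable$cutoff_um)) {
      nearest <- usable[which.min(abs(log(usable$cutoff_um / cutoff_um))), ]
      frac <- nearest$fraction
      flags <- c(flags, "cutoff_clamped")
    } else {
      us <- usable[order(usable$cutoff_um), , drop = FALSE]
      i <- max(which(us$cutoff_um <= cutoff_um))
      z <- stats::qnorm(us$fraction)
      x <- log(us$cutoff_um)
      zi <- z[i] + (log(cutoff_um) - x[i]) * (z[i + 1L] - z[i]) / (x[i + 1L] - x[i])
      frac <- stats::pnorm(zi)
    }
  }
  denom <- if (include_port) recovered_mass(run) else sizing_mass(run)
  list(fpf_percent = 100 * frac * sizing_mass(run) / denom, flags = flags)
}

#' Full aerosol-performance reduction of one impactor run
#'
#' Convenience wrapper producing the standard report: MMAD, GSD, emitted
#' dose and the fine-particle fraction for each requested species, plus the
#' cumulative curve and every flag raised along the way.
#'
#' @param run an [impactor_run()].
#' @param device an [impactor_device()] (cutoffs derived at the run's flow),
#'   or `NULL` if `cutoffs` given.
#' @param cutoffs optional explicit cutoffs overriding the device scaling.
#' @param species character vector of species for FPF.
#' @param include_port FPF denominator choice, see [fpf_by_stage_group()].
#' @param extrapolate passed to [mmad()].
#' @return Object of class `aerosol_performance`.
#' @export
aerosol_performance <- function(run, device = ngi_device(), cutoffs = NULL,
                                species = c("human", "rodent"),
                                include_port = TRUE, extrapolate = FALSE) {
  if (is.null(cutoffs)) cutoffs <- stage_cutoffs(device, run$flow_lpm)
  m <- mmad(run, cutoffs, extrapolate = extrapolate)
  ed <- emitted_dose(run)
  fpf <- vapply(species, function(s)
    fpf_by_stage_group(run, s, include_port = include_port), numeric(1))
  flags <- m$flags
  if (ed$over_recovery) flags <- c(flags, "over_recovery")
  structure(
    list(mmad_um = m$mmad_um, gsd_mmad = m$gsd,
         d84_um = m$d84_um, d16_um = m$d16_um,
         ed_percent = ed$ed_percent,
         fpf_percent_by_species = fpf,
         cumulative_curve = m$curve,
         cutoff_bounds_um = m$bounds,
         flags = flags,
         device = run$device, flow_lpm = run$flow_lpm),
    class = "aerosol_performance"
  )
}

#' @export
print.aerosol_performance <- function(x, ...) {
  cat(sprintf("Aerosol performance: %s at %g L/min\n",
              if (nzchar(x$device)) x$device else "(unnamed device)",
              x$flow_lpm))
  mm <- if (is.na(x$mmad_um))
    sprintf("> %g um (out of stage range)", x$cutoff_bounds_um[2]) else
    sprintf("%.3g um", x$mmad_um)
  gs <- if (is.na(x$gsd_mmad)) "n/a" else sprintf("%.3g", x$gsd_mmad)
  cat(sprintf("  MMAD %s, GSD %s, ED %.4g%%\n", mm, gs, x$ed_percent))
  for (s in names(x$fpf_percent_by_species))
    cat(sprintf("  FPF (%s): %.4g%%\n", s, x$fpf_percent_by_species[[s]]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
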