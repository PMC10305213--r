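# Readers and writers for the package's delimited-text dialects: UTF-8,
# comma-separated, '.' decimal, '#' comment lines, header required.

read_csv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_c <- setdiff(required_cols, names(df))
  if (length(missing_c))
    stop_invalid("file ", path, " is missing column(s): ",
                 paste(missing_c, collapse = ", "))
  df
}

check_numeric_col <- function(df, col, path) {
  x <- df[[col]]
  if (is.character(x)) {
    conv <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(conv) & !is.na(x))
    if (length(bad))
      stop_invalid("non-numeric value in column '", col, "' of ", path,
                   " at data row ", bad[1L], ": '", x[bad[1L]], "'")
    x <- conv
  }
  if (any(is.na(x)))
    stop_invalid("missing value in column '", col, "' of ", path,
                 " at data row ", which(is.na(x))[1L])
  x
}

#' Read a cumulative particle-sizing CSV
#'
#' Expects columns `diameter_um` and `cumulative_percent_undersize`
#' (0--100; converted to fractions). Comment lines start with `#`. Rows at
#' exactly 0% or 100% are dropped with a warning: the probit transform used
#' by [fit_lognormal()] is undefined there, mirroring standard
#' probability-paper practice.
#'
#' @param path CSV path.
#' @return A [cumulative_size_data()] object.
#' @export
read_sizing_csv <- function(path) {
  df <- read_csv_checked(path, c("diameter_um", "cumulative_percent_undersize"))
  d <- check_numeric_col(df, "diameter_um", path)
  pct <- check_numeric_col(df, "cumulative_percent_undersize", path)
  keep <- pct > 0 & pct < 100
  if (any(!keep))
    warn_flag(sum(!keep), " row(s) at 0% or 100% cumulative dropped ",
              "(probit undefined)", class = "aeroperf_dropped_rows")
  if (sum(keep) < 2L)
    stop_invalid("fewer than 2 usable rows in ", path)
  cumulative_size_data(d[keep], pct[keep] / 100, source = basename(path))
}

#' Write a cumulative sizing table as CSV
#'
#' Inverse of [read_sizing_csv()] (fractions written back as percentages).
#'
#' @param data a [cumulative_size_data()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sizing_csv <- function(data, path) {
  stopifnot(inherits(data, "cumulative_size_data"))
  df <- data.frame(diameter_um = data$points$diameter_um,
                   cumulative_percent_undersize =
                     100 * data$points$fraction_undersize)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

impactor_surfaces <- c("induction_port", paste0("stage_", 1:7), "moc")

#' Read an impactor run from CSV plus metadata
#'
#' The CSV has columns `surface` (one row for each of `induction_port`,
#' `stage_1` ... `stage_7`, `moc`) and `mass`. Run metadata (`device`,
#' `flow_lpm`, `loaded_mass`, optional `duration_s`) comes from a YAML
#' sidecar file or an equivalent named list.
#'
#' @param path CSV path.
#' @param sidecar path to a YAML metadata file, or a named list.
#' @return An [impactor_run()].
#' @export
read_impactor_csv <- function(path, sidecar) {
  df <- read_csv_checked(path, c("surface", "mass"))
  mass <- check_numeric_col(df, "mass", path)
  dup <- df$surface[duplicated(df$surface)]
  if (length(dup))
    stop_invalid("duplicated surface(s) in ", path, ": ",
                 paste(unique(dup), collapse = ", "))
  missing_s <- setdiff(impactor_surfaces, df$surface)
  if (length(missing_s))
    stop_invalid("missing surface(s) in ", path, ": ",
                 paste(missing_s, collapse = ", "))
  meta <- if (is.character(sidecar)) {
    if (!file.exists(sidecar)) stop_invalid("sidecar not found: ", sidecar)
    yaml::read_yaml(sidecar)
  } else sidecar
  for (key in c("flow_lpm", "loaded_mass"))
    if (is.null(meta[[key]]))
      stop_invalid("run metadata is missing '", key, "'")
  m <- setNames(mass, df$surface)
  impactor_run(device = meta$device %||% "", flow_lpm = meta$flow_lpm,
               duration_s = meta$duration_s %||% 60,
               loaded_mass = meta$loaded_mass,
               induction_port_mass = m[["induction_port"]],
               stage_masses = unname(m[paste0("stage_", 1:7)]),
               moc_mass = m[["moc"]])
}

#' Write an impactor run as CSV plus YAML sidecar
#'
#' Inverse of [read_impactor_csv()].
#'
#' @param run an [impactor_run()].
#' @param path output CSV path.
#' @param sidecar_path output YAML path (default: `path` with `.yaml`).
#' @return `path`, invisibly.
#' @export
write_impactor_csv <- function(run, path,
                               sidecar_path = sub("\\.csv$", ".yaml", path)) {
  stopifnot(inherits(run, "impactor_run"))
  df <- data.frame(surface = impactor_surfaces,
                   mass = c(run$induction_port_mass, run$stage_masses,
                            run$moc_mass))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(device = run$device, flow_lpm = run$flow_lpm,
                        duration_s = run$duration_s,
                        loaded_mass = run$loaded_mass),
                   sidecar_path)
  invisible(path)
}

#' Read an impactor device definition from YAML
#'
#' Expects keys `name`, `ref_flow_lpm`, `flow_range_lpm` (2 numbers) and
#' `stages`: a list of `{stage, cutoff_um_at_ref, scaling_exponent}`.
#'
#' @param path YAML path.
#' @return An [impactor_device()].
#' @export
read_device_yaml <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  y <- yaml::read_yaml(path)
  for (key in c("name", "ref_flow_lpm", "stages"))
    if (is.null(y[[key]])) stop_invalid("device YAML missing '", key, "'")
  st <- do.call(rbind, lapply(y$stages, as.data.frame))
  st <- st[order(st$stage), ]
  impactor_device(y$name, y$ref_flow_lpm, st$cutoff_um_at_ref,
                  scaling_exponent = st$scaling_exponent %||% 0.5,
                  flow_range_lpm = unlist(y$flow_range_lpm %||% c(10, 100)))
}

#' Read a region scheme from YAML
#'
#' Expects keys `species`, `mode`, `regions` (list of
#' `{name, lo_um, hi_um, generations}`, `hi_um: null` meaning an open top
#' band) and optional `inhalability_cutoff_um`.
#'
#' @param path YAML path.
#' @return A [region_scheme()].
#' @export
read_scheme_yaml <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  y <- yaml::read_yaml(path)
  for (key in c("species", "mode", "regions"))
    if (is.null(y[[key]])) stop_invalid("scheme YAML missing '", key, "'")
  reg <- do.call(rbind, lapply(y$regions, function(r)
    data.frame(name = r$name, lo_um = r$lo_um,
               hi_um = if (is.null(r$hi_um)) Inf else r$hi_um,
               generations = r$generations %||% "")))
  region_scheme(y$species, y$mode, reg,
                inhalability_cutoff_um = y$inhalability_cutoff_um)
}

#' Read a factorial-design CSV with a YAML factor declaration
#'
#' The CSV has one column per factor (actual units) and one response
#' column; the YAML sidecar declares `factors`: a list of
#' `{name, low, high, units}`.
#'
#' @param path CSV path.
#' @param factors_yaml YAML path (or a `data.frame` of factors).
#' @param response response column name.
#' @return A [factorial_design()].
#' @export
read_doe_csv <- function(path, factors_yaml, response) {
  fac <- if (is.character(factors_yaml)) {
    if (!file.exists(factors_yaml))
      stop_invalid("file not found: ", factors_yaml)
    y <- yaml::read_yaml(factors_yaml)
    if (is.null(y$factors)) stop_invalid("factors YAML missing 'factors'")
    do.call(rbind, lapply(y$factors, function(f)
      data.frame(name = f$name, low = f$low, high = f$high,
                 units = f$units %||% "")))
  } else factors_yaml
  df <- read_csv_checked(path, c(fac$name, response))
  for (col in c(fac$name, response)) df[[col]] <- check_numeric_col(df, col, path)
  factorial_design(df, fac, response = response)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble and write a full analysis report for one impactor run
#'
#' Runs the complete reduction ([aerosol_performance()]) and, when the
#' fitted MMAD/GSD are in range, the regional deposition prediction on each
#' supplied scheme with the MMAD-based size distribution. The report is a
#' plain list (written as JSON, with the deposition table also as CSV when
#' `out_dir` is given); every flag raised upstream is carried verbatim, and
#' the report records the package version and a `schema_version` for
#' downstream stability.
#'
#' @param run an [impactor_run()].
#' @param device an [impactor_device()].
#' @param schemes named list of [region_scheme()] objects (may be empty).
#' @param species species for FPF computation.
#' @param out_dir optional output directory for `report.json` /
#'   `deposition.csv`.
#' @param extrapolate passed to [mmad()].
#' @return The report list, invisibly when writing, visibly otherwise.
#' @export
run_report <- function(run, device = ngi_device(),
                       schemes = list(human = builtin_scheme("human"),
                                      rat = builtin_scheme("rat")),
                       species = c("human", "rodent"), out_dir = NULL,
                       extrapolate = FALSE) {
  perf <- aerosol_performance(run, device, species = species,
                              extrapolate = extrapolate)
  deposition <- NULL
  if (!is.na(perf$mmad_um) && !is.na(perf$gsd_mmad) && perf$gsd_mmad >= 1) {
    psd <- lognormal_psd(perf$mmad_um, max(perf$gsd_mmad, 1), label = "MMAD")
    deposition <- lapply(schemes, function(sc) {
      pred <- predict_regions(psd, sc)
      list(species = sc$species, mode = sc$mode,
           fractions_percent = as.list(pred$fractions_percent),
           residual_percent = pred$residual_percent,
           not_inhaled_percent = if (is.na(pred$not_inhaled_percent)) NULL
                                 else pred$not_inhaled_percent)
    })
  }
  report <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("aeroperf")),
    run = list(device = run$device, flow_lpm = run$flow_lpm,
               duration_s = run$duration_s, loaded_mass = run$loaded_mass),
    performance = list(
      mmad_um = perf$mmad_um, gsd_mmad = perf$gsd_mmad,
      ed_percent = perf$ed_percent,
      fpf_percent_by_species = as.list(perf$fpf_percent_by_species),
      cutoff_bounds_um = perf$cutoff_bounds_um,
      cumulative_curve = perf$cumulative_curve,
      flags = perf$flags),
    deposition = deposition
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
    if (!is.null(deposition)) {
      dep_df <- do.call(rbind, lapply(names(deposition), function(nm) {
        d <- deposition[[nm]]
        data.frame(scheme = nm, region = names(d$fractions_percent),
                   percent = unlist(d$fractions_percent))
      }))
      utils::write.csv(dep_df, file.path(out_dir, "deposition.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    return(invisible(report))
  }
  report
}
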