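# Synthetic-data generators. Every generator is a pure function of its
# arguments plus an explicit integer seed: the RNG state is set locally and
# restored on exit, so calling a generator never perturbs the caller's
# random stream.

with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# sd of log(noise) for a multiplicative lognormal perturbation with a given
# coefficient of variation; mean-one so expectations are unbiased
noise_sdlog <- function(cv) sqrt(log(1 + cv^2))
mult_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- noise_sdlog(cv)
  exp(stats::rnorm(n, mean = -s^2 / 2, sd = s))
}

#' Sample particle diameters from a lognormal PSD
#'
#' Independent lognormal draws with `meanlog = log(median_um)` and
#' `sdlog = log(gsd)`; the empirical geometric mean and geometric SD
#' converge to the PSD parameters as `n` grows.
#'
#' @param psd a [lognormal_psd()].
#' @param n number of particles (`>= 1`).
#' @param seed integer seed; the same seed and arguments give identical
#'   draws.
#' @return Numeric vector of diameters (um).
#' @export
sample_diameters <- function(psd, n, seed) {
  stopifnot(inherits(psd, "lognormal_psd"), n >= 1)
  with_seed(seed,
            stats::rlnorm(n, meanlog = log(psd$median_um),
                          sdlog = log(psd$gsd)))
}

#' Simulate a cumulative particle-sizing dataset
#'
#' Emulates a cumulative size measurement (image counts or laser
#' diffraction): the model cumulative fraction at each probe diameter,
#' perturbed by mean-one multiplicative noise with coefficient of variation
#' `noise_cv`, then re-monotonized and clamped inside (0, 1).
#' `noise_cv = 0` returns the exact model values.
#'
#' @param psd ground-truth [lognormal_psd()].
#' @param probe_diameters positive, strictly increasing diameters (um) at
#'   which the cumulative curve is observed.
#' @param noise_cv multiplicative noise CV (`>= 0`).
#' @param seed integer seed.
#' @return A [cumulative_size_data()] object.
#' @export
simulate_sizing_dataset <- function(psd, probe_diameters, noise_cv = 0,
                                    seed = 1) {
  stopifnot(is.numeric(probe_diameters), all(probe_diameters > 0))
  if (is.unsorted(probe_diameters, strictly = TRUE))
    stop_invalid("`probe_diameters` must be strictly increasing")
  if (noise_cv < 0) stop_invalid("`noise_cv` must be >= 0")
  p <- fraction_below(psd, probe_diameters)
  p <- with_seed(seed, p * mult_noise(length(p), noise_cv))
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  p <- cummax(p)                      # re-monotonize
  p <- pmin(p, 1 - 1e-9)
  cumulative_size_data(probe_diameters, p,
                       source = sprintf("synthetic (cv=%g, seed=%d)",
                                        noise_cv, as.integer(seed)))
}

#' Simulate a cascade-impactor run with known ground truth
#'
#' Generates the raw surface masses of an NGI experiment from a true
#' aerodynamic size distribution: `loaded_mass * ed_true` is emitted, a
#' `port_fraction` of it lands in the induction port, and the remainder is
#' classified across stages 1-7 and the MOC. Classification is either
#' `"ideal"` (each stage collects exactly the PSD mass between its cutoff
#' and the next larger one; the MOC gets everything below the stage-7
#' cutoff) or `"sigmoid"` (each stage collects with a logistic collection
#' efficiency in log-diameter of the given `steepness`, applied
#' sequentially to a fine quantile discretization of the PSD). Mean-one
#' multiplicative noise with CV `noise_cv` is finally applied per surface,
#' with draws taken in a fixed surface order (port, stages 1-7, MOC) from a
#' single seeded stream.
#'
#' @param psd true aerodynamic [lognormal_psd()].
#' @param device an [impactor_device()].
#' @param flow_lpm operating flow (L/min).
#' @param loaded_mass mass loaded into the device.
#' @param ed_true true emitted fraction in `[0, 1]`.
#' @param port_fraction fraction of emitted mass depositing in the
#'   induction port, in `[0, 1]`.
#' @param noise_cv per-surface multiplicative noise CV.
#' @param seed integer seed.
#' @param collection `"ideal"` or `"sigmoid"`.
#' @param steepness logistic steepness for `"sigmoid"` collection (larger
#'   is closer to ideal; default 25).
#' @param n_quadrature discretization size for the sigmoid model.
#' @param device_label free-text device name stored on the run.
#' @return An [impactor_run()].
#' @examples
#' run <- simulate_impactor_run(lognormal_psd(3, 1.8, "MMAD"), ngi_device(),
#'                              60, loaded_mass = 10, ed_true = 0.8,
#'                              port_fraction = 0.3, seed = 42)
#' mmad(run, stage_cutoffs(ngi_device(), 60))$mmad_um   # ~3.0
#' @export
simulate_impactor_run <- function(psd, device = ngi_device(), flow_lpm = 60,
                                  loaded_mass = 10, ed_true = 0.8,
                                  port_fraction = 0.3, noise_cv = 0,
                                  seed = 1,
                                  collection = c("ideal", "sigmoid"),
                                  steepness = 25, n_quadrature = 20000,
                                  device_label = "simulated") {
  stopifnot(inherits(psd, "lognormal_psd"))
  collection <- match.arg(collection)
  if (ed_true < 0 || ed_true > 1)
    stop_invalid("`ed_true` must lie in [0, 1]")
  if (port_fraction < 0 || port_fraction > 1)
    stop_invalid("`port_fraction` must lie in [0, 1]")
  if (noise_cv < 0) stop_invalid("`noise_cv` must be >= 0")
  cutoffs <- stage_cutoffs(device, flow_lpm)
  emitted <- loaded_mass * ed_true
  port <- emitted * port_fraction
  sizing <- emitted - port
  if (collection == "ideal") {
    edges_hi <- c(Inf, cutoffs[-7L])
    stages <- sizing * vapply(1:7, function(i)
      band_fraction(psd, cutoffs[i], edges_hi[i]), numeric(1))
    moc <- sizing * fraction_below(psd, cutoffs[7L])
  } else {
    u <- (seq_len(n_quadrature) - 0.5) / n_quadrature
    d <- quantile(psd, u)
    w <- rep(sizing / n_quadrature, n_quadrature)
    stages <- numeric(7)
    for (i in 1:7) {
      eff <- stats::plogis(steepness * log(d / cutoffs[i]))
      stages[i] <- sum(w * eff)
      w <- w * (1 - eff)
    }
    moc <- sum(w)
  }
  masses <- c(port, stages, moc)
  masses <- with_seed(seed, masses * mult_noise(9L, noise_cv))
  impactor_run(device = device_label, flow_lpm = flow_lpm,
               loaded_mass = loaded_mass,
               induction_port_mass = masses[1L],
               stage_masses = masses[2:8], moc_mass = masses[9L])
}

#' Simulate a 2^k factorial response table with planted effects
#'
#' Builds the full coded design and generates the response at each corner
#' as `intercept + sum(effect_t / 2 * contrast_t) + N(0, sigma)` for the
#' planted terms; with `sigma = 0` the planted effects are recovered
#' exactly by [estimate_effects()].
#'
#' @param factors `data.frame` with `name`, `low`, `high` (and optional
#'   `units`), as for [factorial_design()].
#' @param planted_effects named numeric vector of effects (response units,
#'   +1-mean minus -1-mean) keyed by term, e.g.
#'   `c(n2_flow = -0.4, "aspiration:feed_conc" = 0.1)`. Interaction keys
#'   must use the factor order of `factors`.
#' @param intercept grand mean of the response.
#' @param sigma Gaussian noise SD.
#' @param seed integer seed.
#' @param replicates number of replicates per corner.
#' @param response_name response column name.
#' @return A [factorial_design()].
#' @export
simulate_doe_table <- function(factors, planted_effects = numeric(0),
                               intercept = 0, sigma = 0, seed = 1,
                               replicates = 1, response_name = "response") {
  if (!"units" %in% names(factors)) factors$units <- ""
  k <- nrow(factors)
  valid <- design_terms(factors$name)
  if (length(planted_effects)) {
    bad <- setdiff(names(planted_effects), valid)
    if (length(bad))
      stop_invalid("unknown planted term(s): ", paste(bad, collapse = ", "),
                   "; valid terms: ", paste(valid, collapse = ", "))
  }
  coded <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  colnames(coded) <- factors$name
  coded <- coded[rep(seq_len(nrow(coded)), each = replicates), , drop = FALSE]
  y <- rep(intercept, nrow(coded))
  for (tm in names(planted_effects))
    y <- y + (planted_effects[[tm]] / 2) * term_contrast(coded, tm)
  if (sigma > 0)
    y <- y + with_seed(seed, stats::rnorm(length(y), sd = sigma))
  runs <- as.data.frame(coded)
  runs[[response_name]] <- y
  factorial_design(runs, factors, response = response_name)
}
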