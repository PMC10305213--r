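# helper: a crafted run whose cumulative curve takes chosen values.
# fractions = cumulative undersize at stage cutoffs 1..7 (decreasing).
run_from_fractions <- function(fractions, total = 100, port = 0, loaded = 100) {
  stopifnot(length(fractions) == 7L, all(diff(fractions) <= 0))
  stage <- c(total * (1 - fractions[1L]),
             -diff(fractions) * total)
  moc <- total * fractions[7L]
  impactor_run("crafted", flow_lpm = 60, loaded_mass = loaded,
               induction_port_mass = port, stage_masses = stage,
               moc_mass = moc)
}

test_that("stage cutoffs scale with the flow power law", {
  dev <- ngi_device()
  expect_equal(stage_cutoffs(dev, 60), dev$stages$cutoff_um_at_ref)
  expect_equal(stage_cutoffs(dev, 15)[2L], 4.46 * (60 / 15)^0.5)
  expect_equal(stage_cutoffs(dev, 15)[2L], 8.92)
  expect_error(stage_cutoffs(dev, 5), "validity range")
  expect_error(stage_cutoffs(dev, 60, override = rep(2, 7)),
               "strictly decreasing")
})

test_that("device constructor rejects non-monotone cutoffs", {
  expect_error(impactor_device("bad", 60, c(8, 9, 3, 2, 1, 0.5, 0.3)),
               "strictly decreasing")
  expect_error(impactor_device("bad", 60, c(8, 4, 2)), "7 stage cutoffs")
})

test_that("cumulative undersize follows the stage-mass bookkeeping", {
  cuts <- stage_cutoffs(ngi_device(), 60)
  all_moc <- impactor_run("x", 60, 10, 0, rep(0, 7), 5)
  expect_equal(cumulative_undersize(all_moc, cuts)$fraction, rep(1, 7))
  uniform <- impactor_run("x", 60, 200, 0, rep(10, 7), 30)
  expect_equal(cumulative_undersize(uniform, cuts)$fraction[1L], 0.90)
  top <- impactor_run("x", 60, 10, 0, c(5, rep(0, 6)), 0)
  expect_equal(cumulative_undersize(top, cuts)$fraction[1L], 0)
  empty <- impactor_run("x", 60, 10, 4, rep(0, 7), 0)
  expect_error(cumulative_undersize(empty, cuts), "zero")
})

test_that("MMAD interpolation is the probit/log bracketing reduction", {
  cuts <- c(32, 16, 8, 4, 2, 1, 0.5)
  # curve: 0.70 at 4 um, 0.30 at 2 um; symmetric probits => geometric mean
  run <- run_from_fractions(c(0.95, 0.90, 0.80, 0.70, 0.30, 0.10, 0.05))
  m <- mmad(run, cuts)
  expect_equal(m$mmad_um, sqrt(8), tolerance = 1e-9)
  expect_length(m$flags, 0)
  # tie rule: cumulative exactly 0.5 at a cutoff returns that cutoff
  tie <- run_from_fractions(c(0.95, 0.90, 0.80, 0.50, 0.30, 0.10, 0.05))
  expect_equal(mmad(tie, cuts)$mmad_um, 4)
})

test_that("ideal synthetic runs round-trip the aerodynamic PSD", {
  dev <- ngi_device()
  cuts <- stage_cutoffs(dev, 60)
  run <- simulate_impactor_run(lognormal_psd(3.0, 1.8), dev, 60,
                               loaded_mass = 10, ed_true = 0.8,
                               port_fraction = 0.3, seed = 5)
  m <- mmad(run, cuts)
  expect_equal(m$mmad_um, 3.0, tolerance = 0.02)
  expect_equal(m$gsd, 1.8, tolerance = 0.05)
})

test_that("quantiles outside the stage range are flagged, not extrapolated silently", {
  dev <- ngi_device()
  cuts <- stage_cutoffs(dev, 28.3)
  # MMAD far above the largest cutoff, as for a direct-administration device
  run <- simulate_impactor_run(lognormal_psd(50, 1.2), dev, 28.3,
                               loaded_mass = 10, ed_true = 0.7,
                               port_fraction = 0, seed = 9)
  m <- mmad(run, cuts)
  expect_true(is.na(m$mmad_um))
  expect_true("mmad_out_of_range" %in% m$flags)
  ext <- mmad(run, cuts, extrapolate = TRUE)
  expect_true("mmad_extrapolated" %in% ext$flags)
  expect_gt(ext$mmad_um, max(cuts))
  expect_equal(ext$mmad_um, 50, tolerance = 0.02)
})

test_that("emitted dose is recovered mass over loaded mass", {
  run <- impactor_run("MicroSprayer", 28.3, loaded_mass = 10,
                      induction_port_mass = 6,
                      stage_masses = rep(0.0995, 7), moc_mass = 0.0005)
  ed <- emitted_dose(run)
  expect_equal(ed$ed_percent, 66.97)
  expect_false(ed$over_recovery)
  none <- impactor_run("x", 60, 10, 0, rep(0, 7), 0)
  expect_equal(emitted_dose(none)$ed_percent, 0)
  over <- impactor_run("x", 60, 5, 5.6, rep(0, 7), 0)
  expect_equal(emitted_dose(over)$ed_percent, 112)
  expect_true(emitted_dose(over)$over_recovery)
  bad <- impactor_run("x", 60, 0, 1, rep(0, 7), 0)
  expect_error(emitted_dose(bad), "loaded_mass")
})

test_that("emitted dose from components equals the stored-total identity", {
  run <- simulate_impactor_run(lognormal_psd(2.5, 1.6), ngi_device(), 60,
                               loaded_mass = 7.3, ed_true = 0.71,
                               port_fraction = 0.4, noise_cv = 0.05, seed = 3)
  total <- run$induction_port_mass + sum(run$stage_masses) + run$moc_mass
  expect_equal(emitted_dose(run)$ed_percent, 100 * total / run$loaded_mass,
               tolerance = 1e-9)
})

test_that("species FPF uses the conventional stage groups", {
  run <- impactor_run("x", 60, 120, 0,
                      stage_masses = c(50, 20, 10, 10, 5, 3, 1), moc_mass = 1)
  expect_equal(fpf_by_stage_group(run, "human"), 30.0)
  expect_equal(fpf_by_stage_group(run, "rodent"), 20.0)
  all_moc <- impactor_run("x", 60, 10, 0, rep(0, 7), 5)
  expect_equal(fpf_by_stage_group(all_moc, "human"), 100)
  expect_equal(fpf_by_stage_group(all_moc, "rodent"), 100)
  all_port <- impactor_run("x", 60, 10, 5, c(0.001, rep(0, 6)), 0)
  expect_lt(fpf_by_stage_group(all_port, "human"), 0.1)
  expect_error(fpf_by_stage_group(run, "canine"), "configured species")
})

test_that("interpolated FPF matches the closed form on ideal runs", {
  dev <- ngi_device()
  run <- simulate_impactor_run(lognormal_psd(2.0, 1.5), dev, 60,
                               loaded_mass = 10, ed_true = 0.8,
                               port_fraction = 0, seed = 2)
  cuts <- stage_cutoffs(dev, 60)
  got <- fpf_interpolated(run, cuts, 4.46)$fpf_percent
  want <- 100 * stats::pnorm(log(4.46 / 2) / log(1.5))
  expect_equal(got, want, tolerance = 0.02 * want)
  # consistency when the cutoff equals a stage cutoff exactly
  curve <- cumulative_undersize(run, cuts)
  expect_equal(fpf_interpolated(run, cuts, cuts[2L])$fpf_percent,
               100 * curve$fraction[2L])
  # below the smallest stage cutoff: clamped with a flag
  below <- fpf_interpolated(run, cuts, 0.05)
  expect_true("cutoff_clamped" %in% below$flags)
})

test_that("stage-group and interpolated FPF agree where a stage cutoff equals the species cutoff", {
  dev <- ngi_device()
  psd <- lognormal_psd(2.6, 1.7)
  # human: stage-2 cutoff is 4.46 um at 60 L/min
  run_h <- simulate_impactor_run(psd, dev, 60, 10, 0.8, 0.25, seed = 4)
  cuts_h <- stage_cutoffs(dev, 60)
  expect_lt(abs(fpf_by_stage_group(run_h, "human") -
                fpf_interpolated(run_h, cuts_h, 4.46)$fpf_percent), 3)
  # rodent: stage-3 cutoff reaches 2.28 um at 60*(2.82/2.28)^2 L/min
  q_r <- 60 * (2.82 / 2.28)^2
  run_r <- simulate_impactor_run(psd, dev, q_r, 10, 0.8, 0.25, seed = 4)
  cuts_r <- stage_cutoffs(dev, q_r)
  expect_lt(abs(fpf_by_stage_group(run_r, "rodent") -
                fpf_interpolated(run_r, cuts_r, 2.28)$fpf_percent), 3)
})

test_that("the full performance reduction assembles all metrics and flags", {
  run <- simulate_impactor_run(lognormal_psd(2.5, 1.7, "MMAD"), ngi_device(),
                               60, loaded_mass = 10, ed_true = 0.75,
                               port_fraction = 0.25, seed = 8)
  perf <- aerosol_performance(run)
  expect_s3_class(perf, "aerosol_performance")
  expect_equal(perf$mmad_um, 2.5, tolerance = 0.02)
  expect_equal(perf$gsd_mmad, 1.7, tolerance = 0.05)
  expect_equal(perf$ed_percent, 75, tolerance = 1e-9)
  expect_named(perf$fpf_percent_by_species, c("human", "rodent"))
  over <- impactor_run("x", 60, 5, 0, c(3, 2, 1, 0.5, 0.2, 0.1, 0.05), 0.01)
  expect_true("over_recovery" %in% aerosol_performance(over)$flags)
})
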