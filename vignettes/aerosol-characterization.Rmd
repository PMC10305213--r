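---
title: "Characterizing inhalable aerosols: size statistics, impactor reduction, and deposition prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing inhalable aerosols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeroperf)
```

## The problem

Whether an inhaled microparticle formulation reaches the alveoli, the
bronchioles, or never makes it past the throat depends on its aerodynamic
size distribution — and on which *expression* of size the experimenter
chooses to trust. A spray-dried powder is routinely characterized three
ways: a geometric diameter `Dg` from microscopy image counts, a volume
diameter `Dv` from laser diffraction, and a mass median aerodynamic
diameter (MMAD) from cascade impaction of the aerosol the actual delivery
device emits. These can disagree wildly (aggregated powders have `Dv` twice
`Dg`; a poorly dispersing device can emit an MMAD ten times either), and
predictions of lung deposition built on the wrong one are a classic source
of failed preclinical studies. `aeroperf` packages the computational side
of this workflow: the lognormal size-distribution mathematics shared by all
three diameters, the reduction of a next-generation impactor (NGI) run to
its performance metrics, diameter-band prediction of regional deposition in
human and rat airways, and two-level factorial analysis of the spray-drying
process parameters that set the particle size in the first place.

## The lognormal model

Aerosol size distributions are modelled throughout as two-parameter
lognormals: a median diameter (in micrometres, the only length unit in the
package) and a geometric standard deviation,

$$\mathrm{GSD} = \sqrt{d_{84}/d_{16}},$$

the ratio of the diameters one (log-scale) standard deviation above and
below the median. The cumulative fraction of the distribution below a
diameter $d$ is $\Phi\!\left(\ln(d/\text{median}) / \ln \mathrm{GSD}\right)$
and its inverse gives the quantiles. `GSD = 1` is the monodisperse limit,
handled as a point mass at the median (cumulative step at the median; a
boundary diameter belongs to the band above it, so band queries remain
additive). Fitting never returns `GSD <= 1`.

Historically the fit is done by plotting cumulative percent undersize on
log-probability paper and reading the 50th/84th percentiles off a straight
line by eye. `fit_lognormal()` formalizes this as ordinary least squares of
the probit of the cumulative fraction on the log diameter, using *all*
usable points rather than two hand-picked ones: deterministic,
reproducible, and exact on data that truly are lognormal.

```{r fit}
psd_true <- lognormal_psd(2.30, 1.65, label = "Dg")
p <- c(0.1, 0.3, 0.5, 0.7, 0.9)
fit <- fit_lognormal(cumulative_size_data(quantile(psd_true, p), p))
fit
```

Two numerical conventions matter here. Cumulative values of exactly 0 or 1
carry no probit information and are dropped (with a warning) before
fitting, as on physical probability paper. And measured cumulative curves
are often *slightly* non-monotone from digitization or assay noise:
decreases up to 0.005 absolute are repaired by isotonic averaging, anything
larger is treated as corrupt data and rejected — a deliberate line between
noise and error.

## Reducing an impactor run

An NGI classifies the emitted aerosol over an induction port (the
throat-mimicking inlet), seven stages with decreasing D50 cutoff
diameters, and a micro-orifice collector (MOC) catching everything below
stage 7. Stage cutoffs depend on the volumetric flow; calibrations exist at
reference flows only, so the shipped device definition
(`ngi_device()`, also as YAML in `inst/extdata/`) stores reference cutoffs
at 60 L/min (8.06 ... 0.34 µm) plus a per-stage power-law scaling exponent,
default 0.5, that users can override with explicit per-flow tables.

The reduction follows compendial practice:

* **Cumulative curve.** At each cutoff, the fraction of the *sizing mass*
  (stages + MOC; the induction port is excluded from this normalization)
  collected on finer surfaces.
* **MMAD and GSD.** Linear interpolation of probit(cumulative) against
  log(cutoff) between the two stages bracketing 50% (and 84.13%/15.87% for
  the GSD). For a true lognormal aerosol this interpolation is exact. A
  cumulative value landing exactly on a stage returns that stage's cutoff.
  Quantiles outside the stage range — routine for direct-administration
  devices whose MMAD can sit far above the coarsest stage — are reported
  as `NA` with an `out_of_range` flag and the bounding cutoff;
  `extrapolate = TRUE` extends the probit line and flags the result, so
  extrapolation is always a visible choice.
* **Emitted dose.** Recovered mass (port + stages + MOC) over loaded mass,
  ×100; values above 100% raise an over-recovery flag rather than being
  clamped.
* **Fine particle fraction.** Two routes: the conventional stage grouping
  (human: 4.46 µm cutoff, stages 3–7 + MOC; small rodent: 2.28 µm, stages
  4–7 + MOC), and probit/log interpolation at an arbitrary exact cutoff for
  flows where no stage cutoff matches the convention. The FPF denominator
  includes the induction port by default (`include_port = FALSE` restricts
  it to classified mass); both conventions are found in practice, so the
  choice is an explicit flag rather than an assumption.

```{r ngi}
run <- simulate_impactor_run(lognormal_psd(2.5, 1.7, "MMAD"), ngi_device(),
                             flow_lpm = 60, loaded_mass = 10, ed_true = 0.75,
                             port_fraction = 0.25, noise_cv = 0.03, seed = 7)
aerosol_performance(run)
```

## Regional deposition prediction

`predict_regions()` maps a fitted distribution onto an airway scheme by
pure diameter-band assignment — no impaction/sedimentation/diffusion
efficiency physics, exactly the table-style calculation practitioners use
for a first-pass prediction. The two built-in passive-inhalation schemes
are data (YAML), not code, so variants such as narrowed cystic-fibrosis
airways can be expressed without code changes:

* **human**: alveoli < 2 µm (Weibel generations 17–23), bronchioles 2–5 µm,
  bronchi 5–7 µm, trachea 7–10 µm; mass above 10 µm is reported as
  *residual* (extrathoracic / not deposited), never forced into the
  trachea.
* **rat**: alveoli < 1 µm, bronchioles 1–2 µm, bronchi 2–3 µm, trachea
  > 3 µm, with a 3 µm nasal inhalability cutoff: rats are obligate nose
  breathers and the nose filters particles above roughly 3 µm.

The rat cutoff admits two readings — mass above 3 µm as tracheal
deposition, or as never inhaled — and the package implements both: the
default `nose_mode = "annotate"` keeps the band's anatomical label and
separately reports `not_inhaled_percent`, while `"strict"` truncates the
bands at the cutoff and moves the filtered mass into the residual. Region
percentages plus residual always sum to 100 exactly.

```{r deposition}
predict_regions(lognormal_psd(2.70, 1.54, "Dg"), builtin_scheme("human"))
```

`compare_bases()` tabulates the same scheme under Dg, Dv and MMAD and
raises a structured warning when any region differs by more than 20
percentage points between bases — the quantitative form of the warning
that basis choice can dominate every other decision in the workflow.

## Factorial analysis of spray drying

Spray-drying parameters (feed concentration, drying-gas flow, aspiration
rate, feed rate) are screened with 2^k full factorial designs. The package
ships the two bundled optimization tables (`doe1_table()`, a 2^3 screening
round; `doe2_table()`, a 2^2 refinement) and implements the standard
analysis chain: effects as contrast means (mean response at the +1 level
minus the −1 level; the coded regression coefficient is half the effect),
half-normal ranking with plotting positions $(i - 0.5)/m$ for reproducible
plots, ANOVA on an explicitly selected subset of terms (sum of squares
$N \cdot \text{effect}^2 / 4$; unselected terms are pooled into the error,
the only way an unreplicated design yields an F-test), and prediction
equations in coded and actual units. Term selection is deliberately a user
decision, mirroring visual selection from the half-normal plot; an
automatic Lenth margin-of-error selector is available but off by default.
Note that a coded interaction expands into its lower-order sub-terms in
actual units, so the actual-units equation is hierarchical by
construction; the two forms agree exactly at every factor setting.

```{r doe}
design <- factorial_design(doe1_table(), doe1_factors(), response = "dg")
estimate_effects(design)
anova_selected(design, c("n2_flow", "aspiration"))
```

## The synthetic-data generator

Bench measurements (microscopy counts, diffraction curves, stage masses)
are emulated by seeded generators so that every reduction step can be
validated against known ground truth:

* `sample_diameters()` — i.i.d. lognormal draws.
* `simulate_sizing_dataset()` — model cumulative fractions at probe
  diameters under mean-one multiplicative noise, re-monotonized.
* `simulate_impactor_run()` — emitted mass split between induction port
  and stages/MOC, classified either ideally (sharp cutoffs: each stage
  collects exactly the band between adjacent cutoffs) or through logistic
  collection-efficiency curves in log diameter of configurable steepness,
  which lets tests probe MMAD bias under non-ideal separation without
  asserting any particular unpublished calibration. Per-surface noise is
  multiplicative lognormal — assay errors scale with mass and masses stay
  non-negative — drawn in a fixed surface order from one stream so adding
  a surface never shifts other draws.
* `simulate_doe_table()` — factorial responses from planted effects plus
  Gaussian noise.

Defaults mirror the bench conditions the package targets: respirable-range
medians (roughly 1–5 µm geometric, GSD 1.15–1.95), NGI flows of
10–80 L/min, emitted fractions below one with a substantial induction-port
share. Every generator is a pure function of its configuration and an
explicit integer seed (the caller's RNG stream is untouched).

What passing these tests shows — and what it does not. Ideal synthetic
runs make the probit interpolation exact, so parameter recovery there
verifies the bookkeeping, not robustness to real stage behaviour:
real impactor data add wall losses, re-entrainment and finite collection
efficiency sharpness, which the sigmoid mode only approximates. Likewise
the deposition predictor reproduces a band-assignment table, not an
airway-physics model: it ignores inspiratory flow, hygroscopic growth and
breathing pattern entirely.

## Problem sizes and numerical choices

Monte-Carlo cross-checks use 1e5 draws (3-standard-error agreement);
simulation studies use 200 replicates; the sigmoid classifier integrates
over a 20 000-point quantile grid — sizes chosen so the full validation
suite runs in seconds while leaving estimator noise well below the
tolerances being asserted. Fits are plain OLS (no iteration, no
initialization); ties in the cumulative curve resolve to the stage cutoff;
degenerate inputs (all-zero sizing mass, saturated ANOVA selections,
single-diameter sizing tables) are classed, named errors rather than NaN
propagation.

## Known limitations

Band-assignment deposition has no flow-rate dependence; direct
administration (insufflation, intratracheal spray) deposition is out of
scope; only unimodal lognormal distributions are representable; and the
shipped NGI scaling law is a convention — serious work at non-reference
flows should supply measured cutoff tables via the `override` argument or
a device YAML.
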