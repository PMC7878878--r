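---
title: "Chronometric analysis of sparse carnivore death assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chronometric analysis of sparse carnivore death assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carnichron)
```

## The problem

Desert caves accumulate bones over millennia. Because sediment inflow is
minimal, the deposits are shallow, bioturbated and unstratified: a bone
picked off the surface of a cave floor may be fifty or fifty thousand years
old. Such a record cannot be read stratigraphically, but it can be read
chronometrically: if every identifiable specimen is radiocarbon dated, the
*distribution of dates* becomes a proxy for how often a taxon died near the
cave through time — the "dates as data" approach. carnichron implements the
full chain of analysis this requires, from calibrated-date densities to a
permutation test of temporal randomness, together with a convex-hull
quantification of human settlement intensity against which faunal change can
be compared, and a forward simulator for validating every stage.

The working model, stated once: the cave record is a *time-random, sparse
sample* of a death assemblage. Sparse, because only a small fraction of
carcasses enter and survive in caves; time-random, because the mixing of the
deposits destroys any ordering. Under this model the dated sample of a taxon
is a set of i.i.d. draws from its deposition intensity through time, and the
null hypothesis of "no community change" is a homogeneous intensity.

Calendar convention everywhere: ages are cal BP, positive backwards,
0 = 1950 CE; "younger than 3400 cal BP" means cal BP < 3400.

## Calibration

A laboratory reports a conventional radiocarbon age $m \pm \sigma_m$. A
calibration curve tabulates the atmospheric radiocarbon age
$\mu(\theta) \pm \sigma_c(\theta)$ for each calendar age $\theta$. The
calibrated density is the standard intercept-free form
$$ p(\theta) \propto
   \frac{\exp\left\{-\,(m-\mu(\theta))^2 /
   2(\sigma_m^2+\sigma_c(\theta)^2)\right\}}
   {\sqrt{\sigma_m^2+\sigma_c(\theta)^2}}, $$
normalised over the curve support on a 1-calendar-year grid (curve knots are
interpolated linearly; curves are typically tabulated at 5–20 yr steps).
Years carrying less than $10^{-6}$ of the maximum mass are dropped and the
density renormalised — this keeps densities compact and does not move
intervals at conventional levels.

Interval summaries are greedy highest-posterior-density sets: years are
accumulated in order of decreasing mass until the target level (default
0.954, the 2-sigma convention) is reached, then merged into disjoint
intervals. The median is the year at which cumulative mass reaches one half;
when it lands exactly between two years the older year is reported (an
arbitrary but fixed rule).

Dates are screened before calibration: a measurement more than
$k\sigma$ (default $k = 2$) beyond the oldest tabulated radiocarbon age is
`beyond_range`; more than $k\sigma$ younger than the youngest is `modern`
(post-bomb). Both are carried through every summary as explicit categories
rather than dropped silently. Post-bomb calibration proper (F14C), reservoir
corrections and mixed curves are out of scope.

```{r calib-example}
curve <- judean_synthetic_curve()
d <- calibrate_date(uncal_date("HE-010-like", 4477, 26), curve)
d
```

## Occurrence summaries

**MNI.** Dated specimens of one taxon found at the same site and dated to
equivalent calibrated 2-sigma intervals plausibly derive from one carcass
and are counted as a single individual. "Equivalent" is operationalised as
*overlapping* 0.954 HPD intervals with transitive closure (single linkage),
because exact interval equality essentially never occurs between distinct
measurements; a stricter mutual-containment rule is available via
`rule = "containment"`. Modern and beyond-range specimens demonstrably
differ in age from every calibrated one, so each counts as its own
occurrence.

**FAD/LAD.** First and last appearances are the oldest and youngest
calibrated medians by default; `mode = "bound"` uses the outer HPD edges of
the extreme specimens instead (the record is a sample, so the median-based
LAD is biased late relative to a true terminal date — the simulator's
parameter-recovery test shows the estimate approaching a hard cutoff from
above as sample size grows).

**Binning.** For the permutation test, dates from one site and taxon closer
than `h` radiocarbon years (single linkage, default `h` = 100) are grouped
into one *bin*, the unit whose taxon mark gets reshuffled. Binning guards
the test against pseudo-replication: five dates on one carcass are one
depositional event, not five. The cutoff that any particular published bin
count corresponds to is generally unknowable, so bin counts should be
reported across a sweep of `h` rather than asserted at one value.

## The mark-permutation test

The summed probability distribution (SPD) of a taxon is the sum of its
bin-averaged calibrated densities. To ask whether a focal taxon's dates are
distributed through time as a random draw from the pooled assemblage, the
test reshuffles taxon marks over bins (`n_sim` times, preserving per-taxon
bin counts), recomputes the focal SPD each time, and compares the observed
SPD to the per-year 2.5%/97.5% envelope. Maximal runs outside the envelope
are the *local deviation intervals*; the *global statistic* is the summed
squared exceedance beyond the envelope (an absolute-value variant is a
flag), and the global p-value is `(1 + #{sims >= observed}) / (n_sim + 1)`.

Two implementation decisions matter for the test's validity, and both were
found empirically during development:

* **The observed assignment joins the envelope ensemble.** The observed
  marks are the identity permutation — one member of the permutation
  distribution. If the envelope is computed from the simulations alone, the
  largest simulations exceed *their own* envelope by construction while the
  observed only exceeds it by beating them, so simulated statistics
  stochastically dominate the observed one and the test's null rejection
  rate collapses toward zero. Building one envelope from all
  `n_sim + 1` units and measuring every unit against it restores
  exchangeability; the null distribution of the p-value is then uniform up
  to ties.

* **Smoothing resolves the envelope on sparse records** (`runm`, default
  100 calendar years, a centred running mean applied to observed and
  simulated SPDs alike). Where only a handful of bins have support, the
  per-year permutation distribution is nearly two-valued (a bin is in or
  out), the 97.5% quantile freezes at the attainable maximum, and no unit
  can ever exceed it — every statistic ties at zero. A modest running mean
  spreads per-bin mass so neighbouring years inform each other and the
  envelope becomes informative. `runm = NULL` disables it.

The per-year z-transform `(observed - sim mean) / sim sd` is computed and
reported alongside the raw-scale envelope (years with zero simulation
variance get z = 0); since the z-transform is monotone per year, envelope
exceedance is the same event on either scale.

### Operating characteristics, and an honest limitation

With the defaults (12-site assemblages, n = 20 dates per taxon, `n_sim` =
199, `runm` = 100), the test holds its size: across 200 exchangeable
two-taxon null assemblages spanning the Holocene the rejection rate at
$\alpha$ = 0.05 is close to nominal (the acceptance suite recomputes this).
Power, however, depends strongly on the *shape* of the departure. A taxon
whose dates concentrate in a narrow window against a broad background is
detected readily. A diffuse millennial shift — a 10:1 step in deposition
rate at 3400 cal BP, sampled at n = 20 — is a harder target for an
envelope-exceedance statistic at centennial bandwidth: much of the signal
sits *inside* the envelope as a broad, individually-unremarkable elevation.
Raising `runm` toward the signal's scale recovers part of this — smoothing
aggregates a broad elevation into something the envelope can see — and a
count-based statistic tuned to a known change point would recover
essentially all of it; but the envelope statistic is the method under
study, so the package reports its power as it is rather than substituting a
different test. The practical reading: a *significant* result from sparse
data is informative; a non-significant one does not license "no change".

## Settlement intensity

Human settlement intensity per historical period is quantified as the area
of the convex hull around the period's site geometries (pooled hull over
all the period's vertices by default, matching the single-outline
convention; a per-site sum is available), converted to hectares by the
shoelace formula, and classified on the ordinal scale: below 0.5 ha low,
0.5–1.0 ha medium (closed at both bounds), above 1.0 ha high; periods with
no geometry are `no_occupation`. Coordinates must be in a projected metric
CRS; the GeoJSON reader refuses inputs whose coordinates fit in the
geographic degree box rather than silently measuring hectares in square
degrees. `ein_gedi_periods()` ships the thirteen-period Ein Gedi oasis
chronology used in the worked example; its Ottoman row is flagged
inconsistent (printed area and class disagree with the thresholds) and is
excluded from numerical checks.

## The synthetic-data generator

The generator formalises the verbal sampling model as the weakest
probabilistic model consistent with it: each taxon has a piecewise-constant
deposition intensity over calendar time (one segment = the homogeneous
null; a rate step = community restructuring), dates are i.i.d. draws from
it, and each draw is pushed through the forward model of the measurement —
`c14_age ~ Normal(mu(theta), sqrt(sigma_curve^2 + sigma_lab^2))`, rounded
to integer radiocarbon years. Laboratory errors are drawn uniformly from
20–30 radiocarbon years, the magnitude typical of AMS dates on Holocene
bone. Specimens are assigned to sites by weighted sampling; the default of
twelve sites mirrors dispersed multi-cave survey records. A truth table of
every true calendar age is always written.

What the generator deliberately does not emulate: inter-specimen dependence
(several dates on one carcass) beyond what the binning step absorbs,
taphonomic loss as a function of age, and real calibration-curve pathology
(multi-century plateaus and reversals). Synthetic curves are identity or
boundedly-wiggly; tests passing on them show the machinery is correct, not
that any particular real-curve artefact is handled gracefully — plateau
behaviour is exercised separately with hand-built reversal curves.

`judean_synthetic_assemblage()` is a fixed table (65 specimens, 14 cave
sites, three carnivore groups) hand-constructed to carry the *structure* of
a published desert-cave carnivore record — counts of modern and
beyond-range dates, one same-site hyena pair and three same-site leopard
clusters that merge under the 2-sigma rule, a single early-Holocene hyena
date against nineteen younger than 3400 cal BP, a leopard record ending
near 3400 cal BP — paired with `judean_synthetic_curve()`. It is synthetic
reference data for end-to-end validation, not laboratory measurements, and
the package documents it as such.

## Numerical choices and degenerate inputs

* Grid: 1 calendar year everywhere; integer-year HPD interval bounds.
* Tail truncation: `1e-6` of the per-density maximum, then renormalise.
* Envelope exceedances below `1e-8` of the envelope scale are treated as
  zero: the observed SPD travels through the same matrix product as the
  simulations precisely so that summation order cannot manufacture
  departures, and the tolerance removes any residue.
* Ties: HPD accumulation breaks probability ties toward the older year;
  the median tie reports the older year; `sd = 0` years get `z = 0`.
* `h = 0` merges only exactly-equal ages; empty taxa give `mni = 0`;
  a taxon with no calibrated dates gets an explicit undefined FAD/LAD, not
  zeros; degenerate hulls (one or two points, collinear sets) have area 0
  without error; a period with no sites classifies as `no_occupation`.
* All randomness flows from one integer seed per entry point; identical
  inputs and seed give byte-identical outputs.

## Problem sizes used in the checks

The test suite and acceptance script run entirely on synthetic data built
at run time: 100 random curves for the calibration oracle, 200 null and 100
step-scenario assemblages (n = 20 dates per taxon, `n_sim` = 199) for the
operating characteristics, 500 round-trip draws for HPD coverage, and the
65-specimen case study with `n_sim` = 999. These sizes were chosen so the
whole suite completes in minutes while keeping Monte Carlo error a small
fraction of the tolerances being checked.
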