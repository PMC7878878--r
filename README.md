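# carnichron

Chronometric analysis of sparse, time-averaged vertebrate death assemblages
in R.

Desert-cave bone accumulations are unstratified: a surface find can be
decades or tens of millennia old, so the record must be read through
radiocarbon dates rather than stratigraphy. Treating the dated sample of
each taxon as a time-random, sparse draw from its deposition intensity
("dates as data"), carnichron provides the full chain of analysis needed to
ask whether a fossil community was restructured through time, and whether
that restructuring tracks human settlement:

* **Calibration** — intercept-free probabilistic calibration of conventional
  radiocarbon ages against any tabulated curve (`.14c`-style files or CSV),
  with the posterior for calendar age θ proportional to
  `exp(-(m - mu(θ))² / 2(σ_m² + σ_c(θ)²)) / sqrt(σ_m² + σ_c(θ)²)` on a
  1-year grid; greedy highest-posterior-density intervals (default level
  0.954, the 2-sigma convention); explicit screening of post-bomb
  (`modern`) and `beyond_range` measurements.
* **Occurrence summaries** — minimum number of individuals (MNI) by
  single-linkage clustering of same-site specimens with overlapping 2-sigma
  intervals; first/last appearance dates (FAD/LAD); fractions of dates
  younger than a threshold; per-cave taxonomic composition.
* **SPDs and the mark-permutation test** — summed probability distributions
  with site-wise binning against pseudo-replication (single-linkage cutoff
  `h` in ¹⁴C yr); a Monte Carlo test that reshuffles taxon marks over bins,
  builds a per-year 95% simulation envelope, reports local deviation
  intervals, z-scores, and a global p-value from the summed squared
  envelope exceedance.
* **Settlement intensity** — convex hulls over per-period site geometries
  (GeoJSON in a metric CRS), shoelace areas in hectares, and the ordinal
  classification low (< 0.5 ha) / medium (0.5–1.0 ha) / high (> 1.0 ha).
* **A forward simulator** — piecewise-constant deposition scenarios,
  the measurement model `c14 ~ N(mu(θ), sqrt(σ_c² + σ_lab²))`, site
  assignment, and settlement-polygon generation, so every stage is testable
  with no external data.

See the methods vignette (`vignettes/carnivore-chronometrics.Rmd`) for the
statistical model, the reasoning behind the envelope-ensemble and smoothing
conventions, and known limitations.

## Worked example

The package ships a synthetic case study: a 65-specimen carnivore
assemblage (23 striped hyena, 23 leopard, 19 fox) across 14 cave sites,
constructed to carry the structure of a published Judean Desert record, and
a matching synthetic calibration curve. It is synthetic reference data, not
laboratory measurements.

```r
library(carnichron)

curve <- judean_synthetic_curve()
rec   <- calibrate_specimens(judean_synthetic_assemblage(), curve)

assign_mni_clusters(rec, "Hyaena hyaena")[c("nisp", "mni")]
#> $nisp [1] 23    $mni [1] 22
fad_lad(rec, "Hyaena hyaena")[c("fad", "lad", "n_modern")]
#> $fad [1] 7208   $lad [1] 126   $n_modern [1] 3
fraction_after(rec, "Hyaena hyaena", 3400)
#> $k [1] 19   $n [1] 20   $fraction [1] 0.95

grp <- rec; grp$taxon <- taxon_group(rec$taxon)
mark_permutation_test(grp, "hyena", n_sim = 999, seed = 42)
#> <perm_test 'hyena': 19/48 bins, n_sim = 999, global p = 0.012>
#>   positive deviation 1587-1364 cal BP
#>   positive deviation 264-92 cal BP
```

Reading: of 23 hyena specimens, 3 are post-bomb and 20 calibrate; one
same-site pair shares a 2-sigma interval, so at least 22 individuals are
represented. 19/20 calibrated hyena dates (95%) are younger than 3400 cal
BP, the hyena record starts near 7200 cal BP, and the permutation test
rejects temporal randomness (p ≈ 0.01), localising the excess of hyena
dates to roughly 1590–1360 cal BP and the last ~260 years — while the same
test on leopard and fox dates finds no departure (p = 1). The settlement
side mirrors this: `tabulate_periods()` over the synthetic Ein Gedi site
polygons reproduces the published per-period areas (e.g. Roman 1.58 ha →
high) exactly.

The numbered scripts under `analysis/` run this case study end to end
(`01_simulate_inputs.R` → `06_operating_characteristics.R`), writing tables
under `results/`; `run_pipeline()` does the same in one call with a
checksummed manifest.

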