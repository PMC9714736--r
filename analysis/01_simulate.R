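#!/usr/bin/env Rscript
# Stage 1 — simulate the two experiments.
#
# Generates the single-factor thermal series (12 temperatures x 3 pairs x 3
# technical reps of 50 eggs, sand-dollar layout; 7 temperatures for the
# urchin layout) and the 3 temperature x 3 pH factorial in which each pair
# is nested in one temperature but crossed with all pH levels. Everything
# downstream (02-05) reads the CSVs written here.

library(echinofert)

seed <- 20260101
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

sand <- design_spec()  # sand-dollar defaults
urchin <- design_spec(species_label = "red_urchin",
                      temperatures = c(8, 10, 12, 14, 16, 22, 28))

truth_sand <- truth_spec(seed = seed)
# urchins: slower sperm, narrower thermal window than sand dollars
truth_urchin <- truth_spec(
  fert_tpc = list(model = "gaussian",
                  params = c(rmax = 0.85, topt = 16.7, a = 6)),
  velocity_tpc = list(model = "gaussian",
                      params = c(rmax = 180, topt = 16, a = 5)),
  motility_tpc = list(model = "gaussian",
                      params = c(rmax = 0.75, topt = 14, a = 7)),
  seed = seed + 1)

sim_sand <- generate_single_factor_assay(sand, truth_sand)
sim_urch <- generate_single_factor_assay(urchin, truth_urchin)
write_assay_csv(sim_sand, "results/data/sand_assay.csv",
                "results/data/sand_velocity.csv")
write_assay_csv(sim_urch, "results/data/urchin_assay.csv",
                "results/data/urchin_velocity.csv")

fact <- design_spec(temperatures = c(8, 16, 24), phs = c(7.1, 7.5, 7.9))
sim_fact <- generate_factorial_assay(fact, truth_spec(seed = seed + 2))
write_assay_csv(sim_fact, "results/data/factorial_assay.csv",
                "results/data/factorial_velocity.csv")

cat(sprintf("single-factor: %d sand-dollar records (%d pairs), %d urchin records (%d pairs)\n",
            nrow(sim_sand$assay), length(unique(sim_sand$assay$pair_id)),
            nrow(sim_urch$assay), length(unique(sim_urch$assay$pair_id))))
cat(sprintf("factorial: %d records over %d cells\n", nrow(sim_fact$assay),
            nrow(unique(sim_fact$assay[c("temperature_c", "ph")]))))
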