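#!/usr/bin/env Rscript
# Stage 5 — multi-stressor factorial statistics.
#
# Aligned rank transform ANOVA on the temperature x pH factorial for each
# reproductive trait, with partial eta squared, Bonferroni pairwise
# contrasts (raw-scale Cohen's d alongside) and the alignment diagnostics.

library(echinofert)

dir.create("results/factorial", recursive = TRUE, showWarnings = FALSE)
assay <- read_assay_csv("results/data/factorial_assay.csv")
vcl <- read.csv("results/kinematics/factorial_vcl.csv")
fert <- aggregate_fertilization(assay)

responses <- list(
  fertilization = factorial_dataset(fert$fertilization_prop,
                                    fert$temperature_c, fert$ph,
                                    fert$pair_id),
  velocity = factorial_dataset(vcl$mean_vcl, vcl$temperature_c, vcl$ph),
  motility = factorial_dataset(vcl$motile_fraction, vcl$temperature_c,
                               vcl$ph))

for (nm in names(responses)) {
  fd <- responses[[nm]]
  res <- art_anova(fd)
  cat(sprintf("\n== %s ==\n", nm)); print(res)
  write.csv(res$anova, sprintf("results/factorial/%s_anova.csv", nm),
            row.names = FALSE)
  post <- rbind(cbind(factor = "temperature",
                      bonferroni_pairwise(fd, "temperature")),
                cbind(factor = "ph", bonferroni_pairwise(fd, "ph")))
  write.csv(post, sprintf("results/factorial/%s_posthoc.csv", nm),
            row.names = FALSE)
}

# rank correlation between fertilization and sperm traits across cells
cm <- condition_means(fert, vcl)
both <- merge(cm$fert, cm$vel, by = c("temperature_c", "ph"))
sv <- spearman_rho(both$measured_phi, both$mean_vcl)
sm <- spearman_rho(both$measured_phi, both$motile_fraction)
cat(sprintf("\nfertilization vs velocity: rho = %.3f (p = %.3g); vs motility: rho = %.3f (p = %.3g)\n",
            sv$rho, sv$p_value, sm$rho, sm$p_value))
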