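#!/usr/bin/env Rscript
# Step 5 — paired statistics on the cohort.
#
# Normality-gated paired comparison (Shapiro-Wilk on the differences,
# then paired t or Wilcoxon signed-rank) of the pre/post seizure counts
# from step 4, and a three-condition repeated-measures ANOVA with
# Greenhouse-Geisser correction on per-condition mean bin counts for the
# same animals cycled through normoxia, hypoxia and hypoxia + CO2.

library(swdquant)

per_animal <- read.csv("results/cohort/psth_per_animal.csv")

cmp <- paired_compare(paired_sample(
  per_animal$animal, per_animal$mean_pre, per_animal$mean_post,
  conditions = c("normoxia", "hypoxia"),
  measure = "SWS count per 5-min bin"))
print(cmp)

# three-condition cohort: each animal measured under all conditions
set.seed(4)
n <- nrow(per_animal)
rates <- c(normoxia = 0.89, hypoxia = 1.73, hypoxia_co2 = 0.84)
m <- sapply(rates, function(r) rpois(n, 3 * r) / 3)
rownames(m) <- per_animal$animal
an <- rm_anova_gg(m)
print(an)

tab <- results_table(list(cmp), "results/cohort/stats.csv")
anova_row <- data.frame(
  comparison = "SWS count per bin across 3 gas conditions",
  F = an$F, df1 = an$df1, df2 = an$df2, epsilon = an$epsilon,
  p_value = an$p_value)
write.csv(anova_row, "results/cohort/stats_rm_anova.csv",
          row.names = FALSE)
write.csv(an$posthoc, "results/cohort/stats_posthoc.csv",
          row.names = FALSE)

cat(sprintf("\nPaired %s: p = %.2g (n = %d)\n", cmp$test_name,
            cmp$p_value, cmp$n))
cat(sprintf("rm-ANOVA: F(%.3f, %.3f) = %.2f, p = %.2g (GG epsilon = %.3f)\n",
            an$df1, an$df2, an$F, an$p_value, an$epsilon))
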