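#!/usr/bin/env Rscript
# Stage 3: two-scale rarefaction.
#
# Site bins are rarefied to a common 500 grains, the regional pools to
# 50,000, so richness is comparable across samples of very different
# counting effort. Bins below the target are reported undefined and
# excluded downstream rather than rarefied to their own total.

library(palaeodiv)

for (level in c("H0", "H2")) {
  site <- binned_counts(
    read.csv(sprintf("results/site_bins_%s.csv", level)),
    read.csv(sprintf("results/site_bins_meta_%s.csv", level)))
  regional <- binned_counts(
    read.csv(sprintf("results/regional_bins_%s.csv", level)),
    read.csv(sprintf("results/regional_bins_meta_%s.csv", level)))

  site_rar <- rarefy_table(site, 500)
  reg_rar <- rarefy_table(regional, 50000)
  write_table(site_rar, sprintf("results/site_rarefied_%s.csv", level))
  write_table(reg_rar, sprintf("results/regional_rarefied_%s.csv", level))

  ok <- reg_rar[reg_rar$defined, ]
  cat(sprintf("[%s] regional richness at 50k grains: %.1f-%.1f types,",
              level, min(ok$expected_richness), max(ok$expected_richness)),
      sprintf(" SD %.3f-%.3f (median %.3f)\n",
              min(ok$sd), max(ok$sd), median(ok$sd)))
  by_reg <- tapply(ok$expected_richness, ok$owner, median)
  cat(sprintf("[%s] median regional richness, Meridional %.0f vs Boreal %.0f\n",
              level, by_reg["MeridionalSubmeridional"], by_reg["Boreal"]))
}
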