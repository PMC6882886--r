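#!/usr/bin/env Rscript
# Stage 2: read the simulated database back through the interchange
# format, harmonise names at H0 and H2, apply the cohort filters and
# bin everything into millennial slices with regional pooling.
#
# This is the bookkeeping backbone: every later statistic works from the
# binned tables written here.

library(palaeodiv)

seqs <- read_counts_long("results/synthetic_epd/counts.csv")
synonyms <- read_synonym_table("results/synthetic_epd/synonyms.csv")

cat(sprintf("read %d sites, %d grains\n", length(seqs),
            sum(vapply(seqs, total_count, 0))))

for (level in c("H0", "H2")) {
  harm <- lapply(seqs, harmonise, table = synonyms, level = level,
                 unmapped_policy = "drop")
  flt <- filter_sites(harm, min_types = 32)
  cat(sprintf("[%s] %d/%d sites pass the 32-type filter\n",
              level, length(flt$retained), length(harm)))
  regions <- site_regions(flt$retained)
  print(table(regions))

  bins <- bin_sites(flt$retained)
  parts <- split_site_vs_regional(bins, min_count = 500)
  pooled <- pool_regional(parts$all_for_region, regions)
  cat(sprintf("[%s] %d site bins (>= 500 grains), %d regional bins, "
              , level, nrow(parts$site_eligible$meta), nrow(pooled$meta)),
      sprintf("largest pool %d grains\n", max(pooled$meta$total)))

  write_table(parts$site_eligible$counts,
              sprintf("results/site_bins_%s.csv", level))
  write_table(parts$site_eligible$meta,
              sprintf("results/site_bins_meta_%s.csv", level))
  write_table(pooled$counts, sprintf("results/regional_bins_%s.csv", level))
  write_table(pooled$meta, sprintf("results/regional_bins_meta_%s.csv", level))
  write_table(flt$report, sprintf("results/cohort_report_%s.csv", level))
}
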