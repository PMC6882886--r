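test_that("regional compositions are simplex vectors with the encoded structure", {
  for (sd_i in c(1, 2)) {
    cfg <- generator_config(seed = sd_i)
    for (rg in c("Boreal", "MeridionalSubmeridional")) {
      p <- composition(rg, 8000, cfg)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))
    }
  }
  cfg <- generator_config()
  trees <- c("Pinus", "Betula", "Quercus", "Alnus", "Corylus", "Ulmus",
             "Tilia", "Fraxinus", "Picea", "Abies", "Fagus", "Carpinus",
             "Salix", "Juniperus", "Populus")
  # before closure starts, herbs outweigh trees in the Temperate regions
  p12 <- composition("TemperateOceanic", 12000, cfg)
  tree_mass <- sum(p12[names(p12) %in% trees])
  expect_lt(tree_mass, 1 - tree_mass)
  # closure raises tree dominance by 7 ka
  p7 <- composition("TemperateOceanic", 7000, cfg)
  expect_gt(sum(p7[names(p7) %in% trees]), tree_mass)
  # effective richness (> 0.1%) lower at closure peak than after opening
  eff <- function(p) sum(100 * p > 0.1)
  expect_lt(eff(p7), eff(composition("TemperateOceanic", 1000, cfg)))
  # Meridional pool richer than Boreal by construction
  expect_gt(eff(composition("MeridionalSubmeridional", 8000, cfg)),
            eff(composition("Boreal", 8000, cfg)))
})

test_that("the encoded slope schedule has the documented shape", {
  cfg <- generator_config()
  s <- true_slope(slice_centres(), cfg)
  names(s) <- slice_centres()
  expect_equal(unname(s["15000"]), cfg$slope_lateglacial)
  expect_gt(s["7000"], s["8000"])   # local maximum at the closure end
  expect_gt(s["7000"], s["6000"])
  expect_gt(s["0"], s["3000"])      # late rise after the opening onset
  expect_equal(unname(s["3000"] - true_slope(3001, cfg)), 0, tolerance = 1e-6)
})

test_that("generation is deterministic in the seed and passes validation", {
  cfg <- generator_config(seed = 2, n_sites_per_region = 2)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$sites, d2$sites)
  d3 <- generate_dataset(generator_config(seed = 3, n_sites_per_region = 2))
  expect_false(identical(d1$counts, d3$counts))

  # every generated dataset passes the io validation path
  seqs <- counts_from_columns(d1$counts)
  expect_equal(sum(vapply(seqs, total_count, 0)), sum(d1$counts$count))
  expect_true(all(d1$counts$count == round(d1$counts$count)))
  expect_true(all(in_study_area(d1$sites$latitude, d1$sites$longitude)))
  expect_equal(as.character(assign_region(d1$sites$latitude,
                                          d1$sites$longitude)),
               d1$sites$region)
})

test_that("zero synonym noise makes H0 harmonisation the identity on names", {
  cfg <- generator_config(seed = 4, n_sites_per_region = 1,
                          synonym_noise = 0, aquatic_rate = 0)
  ds <- generate_dataset(cfg)
  expect_false(any(grepl(" agg\\.", ds$counts$taxon)))
  seqs <- counts_from_columns(ds$counts)
  h <- harmonise(seqs[[1]], ds$synonyms, "H0")
  expect_equal(h$samples, seqs[[1]]$samples[order(seqs[[1]]$samples$age_bp,
                                                  seqs[[1]]$samples$taxon), ],
               ignore_attr = TRUE)
})

test_that("site richness at 500 grains declines with latitude", {
  ds <- generate_dataset(generator_config(seed = 6, n_sites_per_region = 8))
  seqs <- counts_from_columns(ds$counts)
  harm <- lapply(seqs, harmonise, table = ds$synonyms, level = "H0")
  bins <- split_site_vs_regional(bin_sites(harm))$site_eligible
  rar <- rarefy_table(bins, 500)
  rar <- rar[rar$slice_center_bp == 2000 & rar$defined, ]
  lats <- vapply(harm, `[[`, 0.0, "latitude")[rar$owner]
  expect_lt(cor(lats, rar$expected_richness), -0.5)
})

test_that("the small fixture has its hand-checkable structure", {
  fx <- small_fixture()
  expect_equal(sum(fx$counts$count), fx$total_grains)
  expect_equal(nrow(fx$synonyms), 10)
  expect_equal(length(unique(fx$synonyms$h0)), 8)
  got <- richness_by_level(fx$seqs, fx$synonyms)
  expect_equal(unname(got["n_h0"]), 8)
})
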