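test_that("gradient fits match the closed-form OLS and basic contracts", {
  f <- fit_gradient(c(40, 50, 60), c(30, 20, 10), slice = 0)
  expect_equal(f$slope, -1)
  expect_equal(f$r_squared, 1)

  flat <- fit_gradient(c(40, 50, 60), c(7, 7, 7))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  expect_false(fit_gradient(c(40, 50), c(1, 2))$defined)

  set.seed(8)
  lat <- runif(50, 35, 70)
  rich <- 100 - 0.8 * lat + rnorm(50, 0, 4)
  f2 <- fit_gradient(lat, rich)
  oracle <- ols_closed(lat, rich)
  expect_equal(f2$slope, unname(oracle["slope"]), tolerance = 1e-10)
  expect_equal(f2$intercept, unname(oracle["intercept"]), tolerance = 1e-10)
  expect_equal(f2$r_squared, unname(oracle["r2"]), tolerance = 1e-10)

  # invariance to site ordering
  p <- sample(50)
  f3 <- fit_gradient(lat[p], rich[p])
  expect_equal(f3$slope, f2$slope)
})

test_that("a seeded simulation recovers the true slope within its CI", {
  set.seed(1234)
  lat <- runif(200, 35, 70)
  rich <- 120 - 1.2 * lat + rnorm(200, 0, 3)
  f <- fit_gradient(lat, rich)
  ci <- confint(lm(rich ~ lat))[2, ]
  expect_true(ci[1] <= -1.2 && -1.2 <= ci[2])
  expect_lt(abs(f$slope - -1.2), 0.15)
})

test_that("gradient_timeseries tracks slice-varying true slopes", {
  set.seed(77)
  true_slopes <- setNames(seq(-0.4, -1.9, length.out = 16), slice_centres())
  rows <- list()
  lats <- setNames(runif(60, 36, 69), sprintf("S%02d", 1:60))
  for (sl in slice_centres()) {
    rows[[as.character(sl)]] <- data.frame(
      owner = names(lats), slice_center_bp = sl, n_target = 500,
      n_available = 1000,
      expected_richness = 130 + true_slopes[as.character(sl)] * lats +
        rnorm(60, 0, 2),
      sd = 1, defined = TRUE)
  }
  tab <- do.call(rbind, rows)
  g <- gradient_timeseries(tab, lats)
  expect_equal(nrow(g), 16)
  expect_true(all(g$defined))
  expect_true(all(abs(g$slope - true_slopes) < 0.15))
  expect_gt(cor(g$slope, true_slopes, method = "spearman"), 0.95)

  # a slice with two defined sites is flagged undefined
  tab2 <- tab[!(tab$slice_center_bp == 0 & tab$owner %in% names(lats)[-(1:2)]), ]
  g2 <- gradient_timeseries(tab2, lats)
  expect_false(g2$defined[g2$slice_center_bp == 0])
})

test_that("absolute-richness gradients agree in sign with rarefied ones", {
  ds <- generate_dataset(generator_config(seed = 3, n_sites_per_region = 6))
  seqs <- counts_from_columns(ds$counts)
  harm <- lapply(seqs, harmonise, table = ds$synonyms, level = "H0")
  b <- split_site_vs_regional(bin_sites(harm))$site_eligible
  lats <- setNames(vapply(harm, `[[`, 0.0, "latitude"), names(harm))
  ga <- gradient_absolute(b, lats)
  gr <- gradient_timeseries(rarefy_table(b, 500), lats)
  ok <- ga$defined & gr$defined
  expect_gt(sum(ok), 10)
  expect_true(all(sign(ga$slope[ok]) == sign(gr$slope[ok])))
})

test_that("regional gaps difference Meridional against each northern region", {
  mk <- function(owner, sl, e) data.frame(
    owner = owner, slice_center_bp = sl, n_target = 50000,
    n_available = 1e5, expected_richness = e, sd = 1, defined = TRUE)
  tab <- rbind(mk("MeridionalSubmeridional", 0, 100), mk("Boreal", 0, 60),
               mk("TemperateOceanic", 0, 80),
               mk("TemperateContinental", 0, 70))
  gap <- regional_gap(tab)
  row0 <- gap[gap$slice_center_bp == 0, ]
  expect_equal(row0$diff_vs_boreal, 40)
  expect_equal(row0$diff_vs_temperate_oceanic, 20)
  expect_equal(row0$diff_vs_temperate_continental, 30)
  expect_true(all(is.na(gap$diff_vs_boreal[gap$slice_center_bp > 0])))

  eq <- rbind(mk("MeridionalSubmeridional", 0, 50), mk("Boreal", 0, 50),
              mk("TemperateOceanic", 0, 50), mk("TemperateContinental", 0, 50))
  expect_equal(regional_gap(eq)$diff_vs_boreal[1], 0)
})

test_that("beta ratios behave as regional-to-site richness quotients", {
  reg <- rarefy_expected(rep(10, 90), 500)
  site <- rarefy_expected(rep(30, 30), 500)
  expect_equal(beta_ratio(reg, list(site)),
               reg$expected_richness / site$expected_richness)

  # degenerate: the single site IS the regional pool at the same n
  counts <- rpois(40, 30) + 1
  r <- rarefy_expected(counts, 500)
  expect_equal(beta_ratio(r, list(r)), 1)

  expect_true(is.na(beta_ratio(r, list())))

  # regional pool = union of sites, regional n >= site n  =>  ratio >= 1
  set.seed(14)
  for (i in 1:5) {
    sites <- lapply(1:4, function(j) rpois(25, 15) + 1)
    pool <- Reduce(`+`, sites)
    ratio <- beta_ratio(rarefy_expected(pool, 800),
                        lapply(sites, rarefy_expected, n = 300))
    expect_gte(ratio, 1)
  }
})

test_that("beta ratio falls as sites become compositionally identical", {
  # distinct site pools (high beta) vs identical pools (low beta)
  set.seed(15)
  distinct <- lapply(0:3, function(j) {
    v <- numeric(100); v[j * 25 + 1:25] <- rpois(25, 40) + 1; v
  })
  identical_ <- lapply(0:3, function(j) {
    v <- numeric(100); v[1:25] <- rpois(25, 40) + 1; v
  })
  ratio_of <- function(sites) beta_ratio(
    rarefy_expected(Reduce(`+`, sites), 2000),
    lapply(sites, rarefy_expected, n = 400))
  expect_gt(ratio_of(distinct), ratio_of(identical_))
})
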