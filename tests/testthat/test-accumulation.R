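mk_region_bins <- function(comp_per_slice, id = "R") {
  df <- do.call(rbind, lapply(seq_along(comp_per_slice), function(i) {
    cnt <- comp_per_slice[[i]]
    data.frame(site_id = id, latitude = 50, longitude = 10,
               age_bp = (length(comp_per_slice) - i) * 1000,
               taxon = names(cnt), count = unname(cnt))
  }))
  binned_from_long(df)
}

test_that("accumulation runs oldest-first and counts new taxa once", {
  b <- mk_region_bins(list(c(A = 10), c(A = 5, B = 5)))
  acc <- accumulate(b)
  expect_equal(acc$cum_counts, c(10, 20))
  expect_equal(acc$cum_taxa, c(1, 2))
  expect_equal(acc$slice_center_bp, c(1000, 0))

  const <- mk_region_bins(rep(list(c(A = 10, B = 5)), 5))
  acc2 <- accumulate(const)
  expect_true(all(acc2$cum_taxa == 2))
  expect_equal(acc2$cum_counts, cumsum(rep(15, 5)))

  expect_error(accumulate(mk_region_bins(list(c(A = 1)))), "at least 2")
})

test_that("random accumulation equals a brute-force set-union oracle", {
  set.seed(17)
  comps <- lapply(1:8, function(i) {
    taxa <- sample(sprintf("t%02d", 1:30), sample(5:15, 1))
    setNames(rpois(length(taxa), 20) + 1, taxa)
  })
  acc <- accumulate(mk_region_bins(comps))
  seen <- character(0); oc <- 0
  for (i in seq_along(comps)) {
    seen <- union(seen, names(comps[[i]]))
    oc <- oc + sum(comps[[i]])
    expect_equal(acc$cum_taxa[i], length(seen))
    expect_equal(acc$cum_counts[i], oc)
  }
  expect_true(all(diff(acc$cum_taxa) >= 0))

  # invariance to taxon labelling
  relab <- lapply(comps, function(cnt)
    setNames(unname(cnt), chartr("t", "x", names(cnt))))
  acc2 <- accumulate(mk_region_bins(relab))
  expect_equal(acc2$cum_taxa, acc$cum_taxa)
})

exact_curves <- function(slope = 0.185, k = c(R1 = 1.2, R2 = 2.0)) {
  lapply(names(k), function(rg) {
    counts <- round(10^seq(3, 6, length.out = 8))
    structure(data.frame(region = rg,
                         slice_center_bp = seq(15000, by = -1000,
                                               length.out = 8),
                         cum_counts = counts,
                         cum_taxa = k[[rg]] * counts^slope,
                         new_taxa = NA),
              class = c("accumulation_curve", "data.frame"))
  })
}

test_that("exact power-law curves are inverted to machine precision", {
  fit <- fit_common_slope(exact_curves())
  expect_equal(fit$common_slope, 0.185, tolerance = 1e-9)
  expect_lt(max(abs(fit$points$residual)), 1e-12)
  expect_equal(unname(fit$intercepts), log10(c(1.2, 2.0)), tolerance = 1e-9)

  # both derivations agree on exact data
  fit_avg <- fit_common_slope(exact_curves(), method = "average")
  expect_equal(fit_avg$common_slope, 0.185, tolerance = 1e-9)
})

test_that("joint fit degenerates correctly for one or duplicated regions", {
  one <- exact_curves(k = c(R1 = 1.5))
  noisy <- one[[1]]
  set.seed(40)
  noisy$cum_taxa <- noisy$cum_taxa * 10^rnorm(8, 0, 0.02)
  f <- fit_common_slope(list(noisy))
  ols <- ols_closed(log10(noisy$cum_counts), log10(noisy$cum_taxa))
  expect_equal(f$common_slope, unname(ols["slope"]), tolerance = 1e-10)

  twin <- noisy; twin$region <- "R2"
  f2 <- fit_common_slope(list(noisy, twin))
  expect_equal(unname(f2$intercepts[1]), unname(f2$intercepts[2]))
  expect_equal(f2$common_slope, f$common_slope, tolerance = 1e-10)

  bad <- one[[1]]; bad$cum_taxa[1] <- 0
  expect_error(fit_common_slope(list(bad)), "zero cumulative")
})

test_that("residual series expose time-dependent taxon excess", {
  fit <- fit_common_slope(exact_curves())
  rs <- residual_series(fit)
  expect_true(all(abs(rs$residual) < 1e-12))
  expect_equal(rs, rs[order(rs$region, -rs$slice_center_bp), ],
               ignore_attr = TRUE)

  # inject early extra taxa into one region: early residuals positive
  curves <- exact_curves()
  boosted <- curves[[1]]
  boosted$cum_taxa[1:3] <- boosted$cum_taxa[1:3] * 1.5
  fit2 <- fit_common_slope(list(boosted, curves[[2]]))
  r2 <- residual_series(fit2)
  early <- r2[r2$region == "R1", ][1:3, "residual"]
  late <- r2[r2$region == "R1", ][6:8, "residual"]
  expect_true(all(early > 0))
  expect_gt(mean(early), mean(late))
  # residuals of each region sum to ~0 under its own intercept
  fit3 <- fit_common_slope(exact_curves())
  agg <- tapply(fit3$points$residual, fit3$points$region, sum)
  expect_true(all(abs(agg) < 1e-10))
})

test_that("multinomial sampling from a Zipf pool gives slope in (0,1), no time trend", {
  set.seed(55)
  # a long rare tail keeps the curve from saturating within 16 samples
  p <- (1:8000)^-1.4; p <- p / sum(p)
  taxa <- sprintf("t%04d", 1:8000)
  comps <- lapply(1:16, function(i) {
    cnt <- rmultinom(1, 15000, p)[, 1]
    setNames(cnt, taxa)[cnt > 0]
  })
  fit <- fit_common_slope(list(accumulate(mk_region_bins(comps))))
  expect_gt(fit$common_slope, 0)
  expect_lt(fit$common_slope, 1)
  rs <- residual_series(fit)
  trend <- summary(lm(residual ~ slice_center_bp, data = rs))
  expect_gt(trend$coefficients[2, 4], 0.05)   # no significant time trend
})
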