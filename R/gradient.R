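#' Fit the latitudinal richness gradient for one time slice
#'
#' Ordinary least squares of rarefied (or absolute) richness on site
#' latitude. The regression is deliberately unweighted; slope (pollen
#' types per degree latitude) and R-squared together index the strength of
#' the gradient. Fewer than `min_sites` usable sites, or zero latitude
#' spread, gives an undefined fit (flagged, not an error): slope and
#' R-squared are degenerate below three points.
#'
#' @param latitude,richness Numeric vectors of equal length.
#' @param slice Slice centre (years BP) recorded in the output.
#' @param min_sites Minimum number of sites for a reported fit (default 3).
#' @return One-row data frame: `slice_center_bp`, `slope`, `intercept`,
#'   `r_squared`, `n_sites`, `defined`.
#' @export
fit_gradient <- function(latitude, richness, slice = NA_real_, min_sites = 3) {
  ok <- is.finite(latitude) & is.finite(richness)
  latitude <- latitude[ok]; richness <- richness[ok]
  n <- length(latitude)
  undefined <- data.frame(slice_center_bp = slice, slope = NA_real_,
                          intercept = NA_real_, r_squared = NA_real_,
                          n_sites = n, defined = FALSE)
  if (n < min_sites || stats::var(latitude) == 0) return(undefined)
  fit <- stats::lm(richness ~ latitude)
  tss <- sum((richness - mean(richness))^2)
  # collinear (perfect-fit) input is legitimate here; silence summary.lm
  r2 <- if (tss == 0) 0 else suppressWarnings(summary(fit)$r.squared)
  slope <- if (tss == 0) 0 else unname(stats::coef(fit)[2])
  data.frame(slice_center_bp = slice, slope = slope,
             intercept = unname(stats::coef(fit)[1]),
             r_squared = r2, n_sites = n, defined = TRUE)
}

#' Gradient strength through time from a rarefied site table
#'
#' One OLS fit per time slice (0 to 15 ka), using only sites whose
#' rarefaction result is defined at the common grain sum.
#'
#' @param site_rarefied Output of [rarefy_table] on site-level bins.
#' @param latitudes Named vector, site_id -> latitude.
#' @param min_sites Passed to [fit_gradient].
#' @return Data frame of per-slice [fit_gradient] rows.
#' @export
gradient_timeseries <- function(site_rarefied, latitudes, min_sites = 3) {
  out <- lapply(slice_centres(), function(sl) {
    d <- site_rarefied[site_rarefied$slice_center_bp == sl &
                         site_rarefied$defined, , drop = FALSE]
    fit_gradient(latitude = as.numeric(latitudes[d$owner]),
                 richness = d$expected_richness,
                 slice = sl, min_sites = min_sites)
  })
  do.call(rbind, out)
}

#' Gradient of absolute (size-uncorrected) richness through time
#'
#' Companion to [gradient_timeseries] that regresses the raw number of
#' distinct taxa per bin, irrespective of grain total, on latitude; used
#' to check that the rarefaction correction is not creating the pattern.
#'
#' @param site_bins A `binned_counts` of site bins (post size filter).
#' @inheritParams gradient_timeseries
#' @return Data frame of per-slice [fit_gradient] rows.
#' @export
gradient_absolute <- function(site_bins, latitudes, min_sites = 3) {
  cc <- site_bins$counts[site_bins$counts$count > 0, ]
  rich <- stats::aggregate(taxon ~ owner + slice_center_bp, data = cc,
                           FUN = function(t) length(unique(t)))
  names(rich)[3] <- "richness"
  out <- lapply(slice_centres(), function(sl) {
    d <- rich[rich$slice_center_bp == sl, , drop = FALSE]
    fit_gradient(latitude = as.numeric(latitudes[d$owner]),
                 richness = d$richness, slice = sl, min_sites = min_sites)
  })
  do.call(rbind, out)
}

#' Meridional-minus-north regional richness differences
#'
#' The difference between Meridional/Submeridional regional richness and
#' each northern region per time slice, an alternative index of the
#' strength of the latitudinal gradient. Defined only where both regional
#' rarefaction results are defined.
#'
#' @param regional_rarefied Output of [rarefy_table] on regional bins.
#' @return Data frame: `slice_center_bp`, `diff_vs_temperate_oceanic`,
#'   `diff_vs_temperate_continental`, `diff_vs_boreal` (pollen types).
#' @export
regional_gap <- function(regional_rarefied) {
  get <- function(region, sl) {
    d <- regional_rarefied[regional_rarefied$owner == region &
                             regional_rarefied$slice_center_bp == sl &
                             regional_rarefied$defined, ]
    if (nrow(d) == 1) d$expected_richness else NA_real_
  }
  out <- lapply(slice_centres(), function(sl) {
    m <- get("MeridionalSubmeridional", sl)
    data.frame(slice_center_bp = sl,
               diff_vs_temperate_oceanic = m - get("TemperateOceanic", sl),
               diff_vs_temperate_continental = m - get("TemperateContinental", sl),
               diff_vs_boreal = m - get("Boreal", sl))
  })
  do.call(rbind, out)
}

#' Beta diversity as a regional/site richness ratio
#'
#' Regional pooled richness divided by the median site richness measures
#' between-site compositional differentiation: identical sites give a
#' ratio near 1, strongly differentiated sites a large ratio. By default
#' the regional pool is rarefied to 50,000 grains and the sites to 500;
#' both sizes are configurable (see [beta_ratio_series]).
#'
#' @param regional_result A defined `rarefaction_result` for the regional
#'   pool.
#' @param site_results List of `rarefaction_result`s for the contributing
#'   sites.
#' @return The ratio (numeric), or `NA` if the regional result or every
#'   site result is undefined.
#' @export
beta_ratio <- function(regional_result, site_results) {
  if (!isTRUE(regional_result$defined)) return(NA_real_)
  e <- vapply(site_results, function(r)
    if (isTRUE(r$defined)) r$expected_richness else NA_real_, 0.0)
  e <- e[is.finite(e)]
  if (!length(e)) return(NA_real_)
  regional_result$expected_richness / stats::median(e)
}

#' Beta-diversity ratio series per (region, slice)
#'
#' @param regional_rarefied Output of [rarefy_table] on regional bins
#'   (conventionally at n = 50,000).
#' @param site_rarefied Output of [rarefy_table] on site bins
#'   (conventionally at n = 500).
#' @param regions Named vector, site_id -> region.
#' @return Data frame: `region`, `slice_center_bp`, `beta_ratio`,
#'   `n_sites` (count of defined site results used).
#' @export
beta_ratio_series <- function(regional_rarefied, site_rarefied, regions) {
  reg <- regional_rarefied[regional_rarefied$defined, , drop = FALSE]
  if (!nrow(reg)) {
    return(data.frame(region = character(), slice_center_bp = numeric(),
                      beta_ratio = numeric(), n_sites = integer()))
  }
  site_rarefied$region <- as.character(regions[site_rarefied$owner])
  out <- lapply(seq_len(nrow(reg)), function(i) {
    d <- site_rarefied[site_rarefied$region == reg$owner[i] &
                         site_rarefied$slice_center_bp == reg$slice_center_bp[i] &
                         site_rarefied$defined, , drop = FALSE]
    data.frame(region = reg$owner[i], slice_center_bp = reg$slice_center_bp[i],
               beta_ratio = if (nrow(d))
                 reg$expected_richness[i] / stats::median(d$expected_richness)
               else NA_real_,
               n_sites = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$region, out$slice_center_bp), ]
}
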