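#' Default pipeline configuration
#'
#' Aggregates every analysis constant in one place so no threshold is
#' hard-coded in stage logic: hierarchy levels analysed (H0 and H2; H1
#' yields intermediate results and is skipped by default), the
#' minimum-types site filter (32), the minimum bin total for site-based
#' analysis (500 grains), the site and regional rarefaction sums (500 and
#' 50,000), the presence threshold for turnover (0.1%), the number of
#' detrending segments (26), and the region boundary meridians.
#'
#' @param levels Hierarchy levels to run (default `c("H0", "H2")`).
#' @param min_types Site filter threshold.
#' @param min_count Minimum bin total for site-based analysis.
#' @param site_n,regional_n Rarefaction grain sums.
#' @param presence_pct Turnover presence threshold (percent).
#' @param n_segments Detrending segments.
#' @param min_sites Minimum sites per slice for a gradient fit.
#' @param bounds Region boundaries, see [region_bounds].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(levels = c("H0", "H2"), min_types = 32,
                            min_count = 500, site_n = 500,
                            regional_n = 50000, presence_pct = 0.1,
                            n_segments = 26, min_sites = 3,
                            bounds = region_bounds()) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full diversity-gradient analysis
#'
#' Orchestrates harmonisation, cohort selection, binning, two-scale
#' rarefaction, gradient regression, regional differences, beta-diversity
#' ratios, turnover, ordination (detrended and time-constrained) and
#' taxon accumulation, at each requested hierarchy level. Stages never
#' mutate upstream artifacts; a manifest records the record counts at
#' every stage so each output number is traceable to the inputs and
#' configuration.
#'
#' @param seqs Named list of [pollen_sequence] objects (raw names).
#' @param synonyms A [harmonisation_table].
#' @param cfg A [pipeline_config].
#' @param unmapped_policy Passed to [harmonise] (default `"drop"` for
#'   whole-database runs).
#' @return List of class `pipeline_result`, one element per level (e.g.
#'   `$H0`), each containing `cohort`, `site_bins`, `regional_bins`,
#'   `site_rarefied`, `regional_rarefied`, `gradient`,
#'   `gradient_absolute`, `regional_gap`, `beta_ratio`, `turnover`,
#'   `ordination` (per region: DCA and constrained results),
#'   `accumulation` (`curves`, `fit`, `residuals`), `type_counts`,
#'   and a shared top-level `manifest`.
#' @export
run_pipeline <- function(seqs, synonyms, cfg = pipeline_config(),
                         unmapped_policy = "drop") {
  stopifnot(inherits(synonyms, "harmonisation_table"))
  # cohort selection on raw coordinates first
  lat <- vapply(seqs, `[[`, 0.0, "latitude")
  lon <- vapply(seqs, `[[`, 0.0, "longitude")
  inside <- in_study_area(lat, lon, cfg$bounds)
  seqs <- seqs[inside]
  manifest <- list(n_sites_input = length(inside),
                   n_sites_in_area = sum(inside),
                   config = unclass(cfg))

  out <- list()
  for (level in cfg$levels) {
    harm <- lapply(seqs, harmonise, table = synonyms, level = level,
                   unmapped_policy = unmapped_policy)
    flt <- filter_sites(harm, min_types = cfg$min_types)
    kept <- flt$retained
    if (!length(kept))
      stop("[cohort] no site passes the ", cfg$min_types, "-type filter",
           call. = FALSE)
    regions <- site_regions(kept, cfg$bounds)

    binned <- bin_sites(kept)
    parts <- split_site_vs_regional(binned, min_count = cfg$min_count)
    regional <- pool_regional(parts$all_for_region, regions)

    site_rar <- rarefy_table(parts$site_eligible, n = cfg$site_n)
    regional_rar <- rarefy_table(regional, n = cfg$regional_n)

    lats <- stats::setNames(vapply(kept, `[[`, 0.0, "latitude"),
                            names(kept))
    grad <- gradient_timeseries(site_rar, lats, min_sites = cfg$min_sites)
    grad_abs <- gradient_absolute(parts$site_eligible, lats,
                                  min_sites = cfg$min_sites)
    gap <- regional_gap(regional_rar)
    beta <- beta_ratio_series(regional_rar, site_rar, regions)

    per_region <- lapply(stats::setNames(nm = levels(regions)), function(rg) {
      if (!any(regional$meta$owner == rg)) return(NULL)
      rb <- bins_for_owner(regional, rg)
      slices <- sort(rb$meta$slice_center_bp, decreasing = TRUE)
      m <- bin_matrix(rb)
      m <- m[match(paste0(rg, "@", slices), rownames(m)), , drop = FALSE]
      turn <- turnover_series(rb, threshold_pct = cfg$presence_pct)
      ord <- tryCatch(
        dca_axis1(m, transform = "sqrt", n_segments = cfg$n_segments),
        error = function(e) NULL)
      con <- tryCatch(
        constrained_axis1(m, constraint = slices, transform = "sqrt"),
        error = function(e) NULL)
      acc <- tryCatch(accumulate(rb), error = function(e) NULL)
      list(turnover = turn, dca = ord, dcca = con, accumulation = acc)
    })
    per_region <- Filter(Negate(is.null), per_region)

    curves <- Filter(Negate(is.null), lapply(per_region, `[[`, "accumulation"))
    acc_fit <- if (length(curves)) fit_common_slope(curves) else NULL

    out[[level]] <- list(
      cohort = list(report = flt$report, regions = regions),
      site_bins = parts$site_eligible,
      regional_bins = regional,
      site_rarefied = site_rar,
      regional_rarefied = regional_rar,
      gradient = grad,
      gradient_absolute = grad_abs,
      regional_gap = gap,
      beta_ratio = beta,
      turnover = do.call(rbind, c(lapply(per_region, `[[`, "turnover"),
                                  list(make.row.names = FALSE))),
      ordination = lapply(per_region, function(x) x[c("dca", "dcca")]),
      accumulation = list(curves = curves, fit = acc_fit,
                          residuals = if (!is.null(acc_fit))
                            residual_series(acc_fit) else NULL),
      type_counts = richness_by_level(kept, synonyms))
    manifest[[paste0("level_", level)]] <- list(
      n_sites_retained = length(kept),
      n_site_bins = nrow(parts$site_eligible$meta),
      n_regional_bins = nrow(regional$meta),
      grains_total = sum(regional$meta$total))
  }
  structure(c(out, list(manifest = manifest)), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  lv <- setdiff(names(x), "manifest")
  cat("<pipeline_result> levels:", paste(lv, collapse = ", "), "\n")
  for (l in lv) {
    m <- x$manifest[[paste0("level_", l)]]
    cat("  ", l, ": ", m$n_sites_retained, " sites, ", m$n_site_bins,
        " site bins, ", m$n_regional_bins, " regional bins\n", sep = "")
  }
  invisible(x)
}

#' Concordance between two hierarchy levels
#'
#' Rank correlations between the H0 and H2 runs of the main output
#' series, quantifying robustness to taxonomic resolution: the patterns
#' should be similar regardless of the level if they are not driven by
#' identification biases.
#'
#' @param bundle_a,bundle_b Two per-level result lists from the same
#'   [run_pipeline] call (e.g. `res$H0`, `res$H2`).
#' @return Data frame: `output`, `spearman`, `n` (paired values used).
#' @export
compare_levels <- function(bundle_a, bundle_b) {
  pair_series <- function(a, b, key, value) {
    m <- merge(a[c(key, value)], b[c(key, value)], by = key)
    m <- m[stats::complete.cases(m), , drop = FALSE]
    m
  }
  specs <- list(
    gradient_slope = list(a = bundle_a$gradient, b = bundle_b$gradient,
                          key = "slice_center_bp", value = "slope"),
    regional_richness = list(a = bundle_a$regional_rarefied,
                             b = bundle_b$regional_rarefied,
                             key = c("owner", "slice_center_bp"),
                             value = "expected_richness"),
    turnover = list(a = bundle_a$turnover, b = bundle_b$turnover,
                    key = c("owner", "slice_to_bp"), value = "beta_cc_pct"))
  out <- lapply(names(specs), function(nm) {
    s <- specs[[nm]]
    m <- pair_series(s$a, s$b, s$key, s$value)
    if (!nrow(m)) stop("no overlapping slices for '", nm, "'", call. = FALSE)
    v <- m[, setdiff(names(m), s$key)]
    data.frame(output = nm,
               spearman = if (nrow(m) > 1 && stats::sd(v[[1]]) > 0 &&
                              stats::sd(v[[2]]) > 0)
                 stats::cor(v[[1]], v[[2]], method = "spearman")
               else NA_real_,
               n = nrow(m), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
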