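#' Taxon accumulation over a region's time-ordered pooled samples
#'
#' Running totals, oldest slice first, of identified grains and of newly
#' encountered taxa: the regional analogue of a collector's curve, where
#' "effort" is cumulative counting effort across consecutive millennial
#' samples. Both totals are non-decreasing by construction.
#'
#' @param binned A `binned_counts` restricted to one owner (region).
#' @param time_order Only `"oldest_first"` is meaningful for accumulation
#'   curves; kept explicit for clarity.
#' @return Data frame of class `accumulation_curve`: `region`,
#'   `slice_center_bp`, `cum_counts`, `cum_taxa`, `new_taxa`.
#' @export
accumulate <- function(binned, time_order = "oldest_first") {
  stopifnot(inherits(binned, "binned_counts"),
            identical(time_order, "oldest_first"))
  owner <- unique(binned$meta$owner)
  if (length(owner) != 1L)
    stop("accumulate expects bins of a single owner", call. = FALSE)
  slices <- sort(binned$meta$slice_center_bp, decreasing = TRUE)
  if (length(slices) < 2L)
    stop("need at least 2 slices to accumulate", call. = FALSE)
  seen <- character(0)
  cum_counts <- numeric(length(slices))
  cum_taxa <- integer(length(slices))
  new_taxa <- integer(length(slices))
  running <- 0
  for (i in seq_along(slices)) {
    cnt <- bin_counts(binned, owner, slices[i])
    cnt <- cnt[cnt > 0]
    running <- running + sum(cnt)
    fresh <- setdiff(names(cnt), seen)
    seen <- c(seen, fresh)
    cum_counts[i] <- running
    cum_taxa[i] <- length(seen)
    new_taxa[i] <- length(fresh)
  }
  structure(data.frame(region = owner, slice_center_bp = slices,
                       cum_counts = cum_counts, cum_taxa = cum_taxa,
                       new_taxa = new_taxa, stringsAsFactors = FALSE),
            class = c("accumulation_curve", "data.frame"))
}

#' Shared-slope power-law fit to accumulation curves
#'
#' Taxon accumulation against counting effort is close to a power law,
#' i.e. linear in log-log space. A single slope common to all regions with
#' free per-region intercepts is fitted by least squares
#' (`log10(cum_taxa) ~ log10(cum_counts) + region` in dummy-intercept
#' form), so regions of different richness share one sampling-effect
#' exponent. `method = "average"` instead averages per-region OLS slopes
#' and re-fits intercepts at that fixed slope; the joint fit is the
#' default as the statistically standard formulation.
#'
#' @param curves List of [accumulate] outputs (one per region), or a
#'   single such data frame.
#' @param method `"joint"` (default) or `"average"`.
#' @return List of class `powerlaw_fit`: `common_slope`, `intercepts`
#'   (named per region, log10 taxa units), `points` (per-point data frame
#'   with `log_counts`, `log_taxa`, `fitted`, `residual`), `method`.
#' @export
fit_common_slope <- function(curves, method = c("joint", "average")) {
  method <- match.arg(method)
  if (is.data.frame(curves)) curves <- list(curves)
  pts <- do.call(rbind, lapply(curves, function(d)
    d[c("region", "slice_center_bp", "cum_counts", "cum_taxa")]))
  if (any(pts$cum_counts <= 0 | pts$cum_taxa <= 0))
    stop("zero cumulative value: log-log fit undefined", call. = FALSE)
  for (d in curves) if (nrow(d) < 3L)
    stop("each curve needs >= 3 points", call. = FALSE)
  pts$log_counts <- log10(pts$cum_counts)
  pts$log_taxa <- log10(pts$cum_taxa)
  pts$region <- factor(pts$region)
  if (method == "joint") {
    fit <- if (nlevels(pts$region) > 1)
      stats::lm(log_taxa ~ 0 + region + log_counts, data = pts)
    else stats::lm(log_taxa ~ log_counts, data = pts)
    slope <- unname(stats::coef(fit)["log_counts"])
    ic <- if (nlevels(pts$region) > 1)
      stats::coef(fit)[paste0("region", levels(pts$region))]
    else stats::coef(fit)[1]
    names(ic) <- levels(pts$region)
  } else {
    slopes <- vapply(split(pts, pts$region), function(d)
      unname(stats::coef(stats::lm(log_taxa ~ log_counts, data = d))[2]), 0.0)
    slope <- mean(slopes)
    ic <- vapply(split(pts, pts$region), function(d)
      mean(d$log_taxa - slope * d$log_counts), 0.0)
  }
  pts$fitted <- ic[as.character(pts$region)] + slope * pts$log_counts
  pts$residual <- pts$log_taxa - pts$fitted
  structure(list(common_slope = slope, intercepts = ic,
                 points = pts[c("region", "slice_center_bp", "log_counts",
                                "log_taxa", "fitted", "residual")],
                 method = method),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("<powerlaw_fit> common slope ", format(x$common_slope), " (",
      x$method, " fit), ", length(x$intercepts), " region(s)\n", sep = "")
  invisible(x)
}

#' Residuals of the accumulation fit against time
#'
#' The residual of each time step from the shared power law measures the
#' time-dependent deviation from the expected number of taxa: positive
#' residuals mean more taxa than the common sampling effect predicts
#' (e.g. early postglacial immigration), negative residuals fewer.
#'
#' @param fit A [fit_common_slope] result.
#' @return Data frame: `region`, `slice_center_bp`, `residual`
#'   (log10 taxa units), sorted by region then oldest first.
#' @export
residual_series <- function(fit) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  out <- fit$points[c("region", "slice_center_bp", "residual")]
  out$region <- as.character(out$region)
  out <- out[order(out$region, -out$slice_center_bp), ]
  rownames(out) <- NULL
  out
}
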