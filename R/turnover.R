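#' Taxa present above a percentage threshold
#'
#' Inclusion of rarely occurring taxa is decided by a sample-based
#' percentage threshold: a taxon is "present" when its share of the
#' sample's grain total strictly exceeds `threshold_pct` percent (so with
#' the conventional 0.1, a taxon at exactly 0.1% is excluded). Percentages
#' are computed on the full terrestrial sum of the sample. A threshold of
#' 0 keeps every taxon with a positive count.
#'
#' @param counts Named vector of counts for one sample (total > 0).
#' @param threshold_pct Abundance threshold in percent (default 0.1).
#' @return Character vector of taxon names.
#' @export
presence_set <- function(counts, threshold_pct = 0.1) {
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (!length(counts) || total <= 0)
    stop("zero-total sample", call. = FALSE)
  names(counts)[100 * counts / total > threshold_pct]
}

#' Presence/absence turnover between two samples
#'
#' The proportion of the combined taxon list not shared between two
#' samples, \eqn{\beta_{cc} = (b + c)/(a + b + c)}, with `a` the taxa
#' occurring in both samples and `b`, `c` the taxa occurring in only one;
#' multiplied by 100 to express percentage change. Symmetric, bounded in
#' `[0, 100]`, and zero exactly when the sets coincide.
#'
#' @param set_a,set_b Character vectors of taxon names (duplicates
#'   ignored); not both empty.
#' @return List of class `turnover_pair`: `a`, `b`, `c`, `beta_cc_pct`.
#' @export
beta_cc <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (!length(set_a) && !length(set_b))
    stop("beta_cc undefined: both sets empty", call. = FALSE)
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  cc <- length(setdiff(set_b, set_a))
  structure(list(a = a, b = b, c = cc,
                 beta_cc_pct = 100 * (b + cc) / (a + b + cc)),
            class = "turnover_pair")
}

#' @export
print.turnover_pair <- function(x, ...) {
  cat("beta_cc = ", format(x$beta_cc_pct), "% (shared ", x$a,
      ", only-first ", x$b, ", only-second ", x$c, ")\n", sep = "")
  invisible(x)
}

#' Turnover between consecutive regional time slices
#'
#' Computes [beta_cc] between each pair of adjacent slices of one region's
#' pooled series, oldest to youngest, using presence above
#' `threshold_pct` percent.
#'
#' @param binned A `binned_counts` restricted to one owner (region).
#' @param threshold_pct Passed to [presence_set].
#' @return Data frame with one row per adjacent pair: `owner`,
#'   `slice_from_bp`, `slice_to_bp` (younger), `a`, `b`, `c`,
#'   `beta_cc_pct`.
#' @export
turnover_series <- function(binned, threshold_pct = 0.1) {
  stopifnot(inherits(binned, "binned_counts"))
  owner <- unique(binned$meta$owner)
  if (length(owner) != 1L)
    stop("turnover_series expects bins of a single owner", call. = FALSE)
  slices <- sort(binned$meta$slice_center_bp, decreasing = TRUE) # oldest first
  if (length(slices) < 2L) {
    return(data.frame(owner = character(), slice_from_bp = numeric(),
                      slice_to_bp = numeric(), a = integer(), b = integer(),
                      c = integer(), beta_cc_pct = numeric()))
  }
  sets <- lapply(slices, function(sl)
    presence_set(bin_counts(binned, owner, sl), threshold_pct))
  out <- lapply(seq_len(length(slices) - 1L), function(i) {
    p <- beta_cc(sets[[i]], sets[[i + 1L]])
    data.frame(owner = owner, slice_from_bp = slices[i],
               slice_to_bp = slices[i + 1L],
               a = p$a, b = p$b, c = p$c, beta_cc_pct = p$beta_cc_pct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
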