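#' Time-slice centres covering the last 15,000 years
#' @return Numeric vector `c(0, 1000, ..., 15000)` (years BP).
#' @export
slice_centres <- function() seq(0, 15000, by = 1000)

# binned counts are carried as a pair of aligned data frames:
#   counts: owner, slice_center_bp, taxon, count  (long, count > 0)
#   meta:   owner, slice_center_bp, total, n_samples
new_binned <- function(counts, meta) {
  structure(list(counts = counts, meta = meta), class = "binned_counts")
}

#' Assemble a binned-counts object from its two tables
#'
#' Constructor for the container produced by [bin_site]/[pool_regional],
#' used to rebuild binned data from exported CSVs. `meta` is derived
#' from `counts` when omitted (then `n_samples` is unknown and set to
#' `NA`); when given, totals are checked against the counts.
#'
#' @param counts Data frame `owner`, `slice_center_bp`, `taxon`, `count`.
#' @param meta Optional data frame `owner`, `slice_center_bp`, `total`,
#'   `n_samples`.
#' @return A `binned_counts` object.
#' @export
binned_counts <- function(counts, meta = NULL) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("owner", "slice_center_bp", "taxon", "count") %in%
                  names(counts)))
  counts <- counts[counts$count > 0, , drop = FALSE]
  tot <- stats::aggregate(count ~ owner + slice_center_bp, data = counts,
                          FUN = sum)
  names(tot)[3] <- "total"
  if (is.null(meta)) {
    meta <- tot
    meta$n_samples <- NA_integer_
  } else {
    meta <- as.data.frame(meta)
    stopifnot(all(c("owner", "slice_center_bp", "total") %in% names(meta)))
    if (!"n_samples" %in% names(meta)) meta$n_samples <- NA_integer_
    chk <- merge(meta, tot, by = c("owner", "slice_center_bp"),
                 suffixes = c("", ".from_counts"))
    if (any(chk$total != chk$total.from_counts))
      stop("meta totals disagree with summed counts", call. = FALSE)
  }
  o <- order(counts$owner, counts$slice_center_bp, counts$taxon)
  new_binned(counts[o, ], meta[order(meta$owner, meta$slice_center_bp), ])
}

#' Restrict a binned-counts object to one owner
#' @param binned A `binned_counts`.
#' @param owner Site id or region name.
#' @return A `binned_counts` holding only that owner's bins.
#' @export
bins_for_owner <- function(binned, owner) {
  stopifnot(inherits(binned, "binned_counts"))
  new_binned(binned$counts[binned$counts$owner == owner, , drop = FALSE],
             binned$meta[binned$meta$owner == owner, , drop = FALSE])
}

#' @export
print.binned_counts <- function(x, ...) {
  cat("<binned_counts> ", nrow(x$meta), " (owner, slice) bins, ",
      length(unique(x$counts$taxon)), " taxa, ",
      sum(x$meta$total), " grains\n", sep = "")
  invisible(x)
}

#' Bin a dated pollen sequence into 1000-year time slices
#'
#' Each raw sample is atomic: its point age assigns it to exactly one
#' slice, the 1000-year window centred on a full millennium. The window is
#' half-open, `[c - 500, c + 500)`, so an age of exactly 1500 BP falls in
#' the 2000 BP slice and no sample is counted twice. Slices run 0 to
#' 15,000 BP inclusive; samples older than 15,500 BP (or younger than
#' -500, which cannot occur for real ages) are discarded. Counts are
#' summed per slice and the number of contributing raw samples recorded.
#'
#' @param seq A harmonised [pollen_sequence].
#' @return A `binned_counts` object with `owner = site_id`; empty slices
#'   are absent.
#' @export
bin_site <- function(seq) {
  stopifnot(inherits(seq, "pollen_sequence"))
  s <- seq$samples
  slice <- 1000 * floor((s$age_bp + 500) / 1000)
  keep <- slice >= 0 & slice <= 15000
  s <- s[keep, , drop = FALSE]
  slice <- slice[keep]
  if (!nrow(s)) {
    return(new_binned(
      counts = data.frame(owner = character(), slice_center_bp = numeric(),
                          taxon = character(), count = numeric()),
      meta = data.frame(owner = character(), slice_center_bp = numeric(),
                        total = numeric(), n_samples = integer())))
  }
  counts <- stats::aggregate(count ~ slice_center_bp + taxon,
                             data = data.frame(slice_center_bp = slice,
                                               taxon = s$taxon,
                                               count = s$count),
                             FUN = sum)
  counts <- counts[counts$count > 0, , drop = FALSE]
  n_samp <- tapply(s$age_bp, slice, function(a) length(unique(a)))
  tot <- tapply(s$count, slice, sum)
  meta <- data.frame(owner = seq$site_id,
                     slice_center_bp = as.numeric(names(tot)),
                     total = as.numeric(tot),
                     n_samples = as.integer(n_samp[names(tot)]),
                     row.names = NULL)
  counts <- data.frame(owner = seq$site_id,
                       slice_center_bp = counts$slice_center_bp,
                       taxon = counts$taxon, count = counts$count,
                       stringsAsFactors = FALSE)
  o <- order(counts$slice_center_bp, counts$taxon)
  new_binned(counts[o, ], meta[order(meta$slice_center_bp), ])
}

#' Bin every site in a set
#' @param seqs List of harmonised [pollen_sequence] objects.
#' @return A single `binned_counts` holding all sites' bins.
#' @export
bin_sites <- function(seqs) {
  parts <- lapply(seqs, bin_site)
  new_binned(do.call(rbind, c(lapply(parts, `[[`, "counts"),
                              list(make.row.names = FALSE))),
             do.call(rbind, c(lapply(parts, `[[`, "meta"),
                              list(make.row.names = FALSE))))
}

#' Split bins into site-analysis and regional-pool sets
#'
#' Bins with fewer than `min_count` grains carry too much sampling noise
#' for site-level rarefaction and are excluded from site-based analysis,
#' but their grains still contribute to the regional pool.
#'
#' @param binned A `binned_counts` object.
#' @param min_count Minimum grain total for site-based analysis
#'   (default 500).
#' @return List with `site_eligible` (bins with `total >= min_count`) and
#'   `all_for_region` (every bin, unchanged).
#' @export
split_site_vs_regional <- function(binned, min_count = 500) {
  stopifnot(inherits(binned, "binned_counts"))
  ok <- binned$meta$total >= min_count
  key <- paste(binned$meta$owner, binned$meta$slice_center_bp)
  ckey <- paste(binned$counts$owner, binned$counts$slice_center_bp)
  keep <- ckey %in% key[ok]
  list(site_eligible = new_binned(binned$counts[keep, , drop = FALSE],
                                  binned$meta[ok, , drop = FALSE]),
       all_for_region = binned)
}

#' Pool site bins into regional samples
#'
#' Sums pollen identifications over all sites of a region within each time
#' slice; grain totals are conserved and the number of contributing raw
#' samples recorded. Regional pools can reach the order of 1e7 grains.
#'
#' @param binned A `binned_counts` of site bins.
#' @param regions Named factor/character, site_id -> region
#'   (see [site_regions]).
#' @return A `binned_counts` with `owner = region`.
#' @export
pool_regional <- function(binned, regions) {
  stopifnot(inherits(binned, "binned_counts"))
  miss <- setdiff(unique(binned$meta$owner), names(regions))
  if (length(miss))
    stop("site without region assignment: '", miss[1], "'", call. = FALSE)
  cc <- binned$counts
  cc$owner <- as.character(regions[cc$owner])
  counts <- stats::aggregate(count ~ owner + slice_center_bp + taxon,
                             data = cc, FUN = sum)
  mm <- binned$meta
  mm$owner <- as.character(regions[mm$owner])
  meta <- stats::aggregate(cbind(total = total, n_samples = n_samples)
                           ~ owner + slice_center_bp, data = mm, FUN = sum)
  o <- order(counts$owner, counts$slice_center_bp, counts$taxon)
  new_binned(counts[o, ], meta[order(meta$owner, meta$slice_center_bp), ])
}

#' Extract one bin's counts as a named vector
#' @param binned A `binned_counts`.
#' @param owner,slice Bin key.
#' @return Named numeric vector of counts (possibly empty).
#' @export
bin_counts <- function(binned, owner, slice) {
  sel <- binned$counts$owner == owner & binned$counts$slice_center_bp == slice
  stats::setNames(binned$counts$count[sel], binned$counts$taxon[sel])
}

#' Wide count matrix for a set of bins
#'
#' Rows are (owner, slice) cells labelled `"owner@slice"`, columns taxa;
#' the carrier format for ordination and export.
#'
#' @param binned A `binned_counts`.
#' @return Integer-valued matrix with dimnames.
#' @export
bin_matrix <- function(binned) {
  cc <- binned$counts
  rows <- paste0(cc$owner, "@", cc$slice_center_bp)
  rlev <- paste0(binned$meta$owner, "@", binned$meta$slice_center_bp)
  clev <- sort(unique(cc$taxon))
  m <- matrix(0, nrow = length(rlev), ncol = length(clev),
              dimnames = list(rlev, clev))
  m[cbind(match(rows, rlev), match(cc$taxon, clev))] <- cc$count
  m
}
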