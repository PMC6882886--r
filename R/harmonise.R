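#' Construct and validate a harmonisation table
#'
#' Validates the nesting structure of a synonym/hierarchy table: every
#' original name appears exactly once; accepted names are non-blank; H1
#' coarsens H0 (two originals sharing an H0 name share an H1 name), H2
#' coarsens H1; and the inclusion flag is constant within an H0 group.
#' Violations in a user-supplied table are an error at load, not silently
#' tolerated: the levels are strictly nested by construction.
#'
#' @param df Data frame with columns `original`, `h0`, `h1`, `h2`,
#'   `include` (logical).
#' @return The validated table with class `harmonisation_table`.
#' @export
harmonisation_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("original", "h0", "h1", "h2", "include")
  stopifnot(all(need %in% names(df)))
  df <- df[need]
  for (col in c("original", "h0", "h1", "h2")) df[[col]] <- as.character(df[[col]])
  df$include <- as.logical(df$include)
  if (any(is.na(df$include))) stop("include flag must be logical", call. = FALSE)
  for (col in c("h0", "h1", "h2")) {
    if (any(is.na(df[[col]]) | !nzchar(trimws(df[[col]]))))
      stop("blank accepted name in column '", col, "'", call. = FALSE)
  }
  # exact duplicate rows collapse; conflicting duplicates are an error
  df <- unique(df)
  dup <- df$original[duplicated(df$original)]
  if (length(dup))
    stop("duplicate original name with conflicting targets: '", dup[1], "'",
         call. = FALSE)
  .check_nested(df, "h0", "h1")
  .check_nested(df, "h1", "h2")
  .check_nested(df, "h0", "include")
  rownames(df) <- NULL
  structure(df, class = c("harmonisation_table", "data.frame"))
}

.check_nested <- function(df, fine, coarse) {
  n_target <- tapply(df[[coarse]], df[[fine]], function(v) length(unique(v)))
  bad <- names(n_target)[n_target > 1]
  if (length(bad))
    stop("hierarchy violation: '", fine, "' group '", bad[1],
         "' maps to several '", coarse, "' values", call. = FALSE)
  invisible(TRUE)
}

.level_col <- function(level) {
  lev <- tolower(as.character(level))
  if (!lev %in% c("h0", "h1", "h2"))
    stop("level must be one of H0, H1, H2", call. = FALSE)
  lev
}

#' Harmonise a pollen sequence to an accepted taxonomy level
#'
#' Re-keys every sample's counts to the accepted names at the requested
#' hierarchy level, summing counts where several original names map to one
#' accepted name, and removing taxa excluded from the terrestrial
#' pollen-and-spore sum (`include = FALSE`).
#'
#' @param seq A [pollen_sequence].
#' @param table A [harmonisation_table].
#' @param level `"H0"`, `"H1"` or `"H2"`.
#' @param unmapped_policy What to do with original names absent from the
#'   table: `"error"` (default) stops naming the first offending taxon;
#'   `"drop"` removes them with a warning and records them in the
#'   `"unmapped"` attribute of the result (the audit list).
#' @return A harmonised [pollen_sequence]; attribute `"unmapped"` holds
#'   the dropped original names (empty unless `unmapped_policy = "drop"`).
#' @export
harmonise <- function(seq, table, level = c("H0", "H1", "H2"),
                      unmapped_policy = c("error", "drop")) {
  stopifnot(inherits(seq, "pollen_sequence"),
            inherits(table, "harmonisation_table"))
  level <- .level_col(match.arg(toupper(level[1]), c("H0", "H1", "H2")))
  unmapped_policy <- match.arg(unmapped_policy)
  if (nrow(seq$samples) == 0L) stop("empty pollen sequence", call. = FALSE)

  idx <- match(seq$samples$taxon, table$original)
  unmapped <- sort(unique(seq$samples$taxon[is.na(idx)]))
  if (length(unmapped)) {
    if (unmapped_policy == "error")
      stop("unmapped taxon name: '", unmapped[1], "'", call. = FALSE)
    warning("dropping ", length(unmapped), " unmapped taxon name(s) from site '",
            seq$site_id, "'", call. = FALSE)
  }
  keep <- !is.na(idx) & table$include[idx]
  s <- seq$samples[keep, , drop = FALSE]
  s$taxon <- table[[level]][idx[keep]]
  if (nrow(s)) {
    s <- stats::aggregate(count ~ age_bp + taxon, data = s, FUN = sum)
  }
  out <- pollen_sequence(site_id = seq$site_id, site_name = seq$site_name,
                         latitude = seq$latitude, longitude = seq$longitude,
                         elevation_m = seq$elevation_m,
                         samples = s[order(s$age_bp, s$taxon), , drop = FALSE])
  attr(out, "unmapped") <- unmapped
  out
}

#' Distinct included type counts at each hierarchy level
#'
#' Counts the distinct accepted names actually used by a dataset at H0, H1
#' and H2, restricted to included (terrestrial) taxa mapped by the table.
#' By nesting, `n_h0 >= n_h1 >= n_h2`. Unmatched names are ignored here
#' (the counts describe the matched, post-selection dataset).
#'
#' @param seqs A [pollen_sequence] or list of them.
#' @param table A [harmonisation_table].
#' @return Named integer vector `c(n_h0, n_h1, n_h2)`.
#' @export
richness_by_level <- function(seqs, table) {
  stopifnot(inherits(table, "harmonisation_table"))
  if (inherits(seqs, "pollen_sequence")) seqs <- list(seqs)
  nm <- unique(unlist(lapply(seqs, function(s)
    s$samples$taxon[s$samples$count > 0])))
  idx <- match(nm, table$original)
  idx <- idx[!is.na(idx)]
  idx <- idx[table$include[idx]]
  c(n_h0 = length(unique(table$h0[idx])),
    n_h1 = length(unique(table$h1[idx])),
    n_h2 = length(unique(table$h2[idx])))
}
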