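#' Construct a pollen sequence
#'
#' A `pollen_sequence` holds one site's metadata together with its dated
#' samples of taxon counts in long form. Ages are calibrated years before
#' present (BP, present = 1950 CE); negative ages (post-1950) are accepted
#' but flagged with a warning at read time.
#'
#' @param site_id Opaque site identifier (string).
#' @param latitude,longitude Site coordinates in decimal degrees
#'   (latitude N, longitude E; negative = W). Required: region assignment
#'   and the latitudinal gradient need them.
#' @param samples Data frame with columns `age_bp`, `taxon`, `count`.
#'   Counts must be non-negative integers; duplicate `(age_bp, taxon)`
#'   rows are not allowed (sum them before construction).
#' @param site_name Optional human-readable name.
#' @param elevation_m Optional elevation in metres (`NA` tolerated).
#' @return An object of class `pollen_sequence`.
#' @export
pollen_sequence <- function(site_id, latitude, longitude, samples,
                            site_name = site_id, elevation_m = NA_real_) {
  stopifnot(is.character(site_id), length(site_id) == 1L, nzchar(site_id))
  if (!is.finite(latitude) || !is.finite(longitude))
    stop("site '", site_id, "': missing or non-finite coordinates", call. = FALSE)
  if (latitude < -90 || latitude > 90)
    stop("site '", site_id, "': latitude out of [-90, 90]", call. = FALSE)
  if (longitude < -180 || longitude > 180)
    stop("site '", site_id, "': longitude out of [-180, 180]", call. = FALSE)
  samples <- as.data.frame(samples)
  need <- c("age_bp", "taxon", "count")
  if (!all(need %in% names(samples)))
    stop("samples must have columns age_bp, taxon, count", call. = FALSE)
  samples$taxon <- as.character(samples$taxon)
  .check_counts(samples$count, context = paste0("site '", site_id, "'"))
  if (anyDuplicated(samples[c("age_bp", "taxon")]))
    stop("site '", site_id, "': duplicate (age_bp, taxon) rows", call. = FALSE)
  samples <- samples[c("age_bp", "taxon", "count")]
  rownames(samples) <- NULL
  structure(
    list(site_id = site_id, site_name = site_name,
         latitude = latitude, longitude = longitude,
         elevation_m = elevation_m, samples = samples),
    class = "pollen_sequence")
}

#' @export
print.pollen_sequence <- function(x, ...) {
  cat("<pollen_sequence> ", x$site_id, " (", format(x$latitude), "N, ",
      format(x$longitude), "E)\n", sep = "")
  cat("  ", length(unique(x$samples$age_bp)), " samples, ",
      length(unique(x$samples$taxon[x$samples$count > 0])), " taxa, ",
      sum(x$samples$count), " grains\n", sep = "")
  invisible(x)
}

#' Total grain count of a pollen sequence
#' @param seq A `pollen_sequence`.
#' @return Integer-valued total of all counts.
#' @export
total_count <- function(seq) {
  stopifnot(inherits(seq, "pollen_sequence"))
  sum(seq$samples$count)
}

.check_counts <- function(counts, context = "counts") {
  if (!is.numeric(counts))
    stop(context, ": counts must be numeric", call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad))
    stop(context, ": non-integer or negative count at row ", bad[1],
         " (value ", counts[bad[1]], ")", call. = FALSE)
  invisible(TRUE)
}

.default_count_schema <- function() {
  list(site_id = "site_id", site_name = "site_name",
       latitude = "latitude", longitude = "longitude",
       elevation_m = "elevation_m",
       age_bp = "age_bp", taxon = "taxon", count = "count")
}

#' Read a long-format pollen count table
#'
#' Reads a tidy CSV (one row per site, sample age and taxon) into a set of
#' [pollen_sequence] objects. The interchange format is UTF-8,
#' comma-separated, with a mandatory header row; sparse data stay compact
#' because absent taxa are simply absent rows.
#'
#' Counts for repeated `(site, age, taxon)` rows are summed with a warning
#' (different analysts sometimes split one count over several rows).
#' Missing coordinates are an error; missing elevation is tolerated.
#' Negative ages (samples younger than 1950 CE) are accepted with a warning.
#'
#' @param path CSV file path.
#' @param schema Named list mapping the canonical field names
#'   (`site_id`, `latitude`, `longitude`, `age_bp`, `taxon`, `count`, and
#'   optionally `site_name`, `elevation_m`) to the column names used in the
#'   file. Defaults to the canonical names themselves.
#' @return Named list of [pollen_sequence] objects, one per site id.
#' @export
read_counts_long <- function(path, schema = NULL) {
  sch <- .default_count_schema()
  if (!is.null(schema)) sch[names(schema)] <- schema
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("site_id", "latitude", "longitude", "age_bp", "taxon", "count")
  for (f in required) {
    if (!sch[[f]] %in% names(df))
      stop("missing required column '", sch[[f]], "' in ", path, call. = FALSE)
  }
  counts_from_columns(df, schema = sch, source = path)
}

#' Build pollen sequences from an in-memory long table
#'
#' Same contract as [read_counts_long] but starting from a data frame,
#' used by the synthetic generator and by callers that assemble tables
#' themselves.
#'
#' @param df Long-format data frame.
#' @inheritParams read_counts_long
#' @param source Label used in error messages.
#' @return Named list of [pollen_sequence] objects.
#' @export
counts_from_columns <- function(df, schema = NULL, source = "data") {
  sch <- .default_count_schema()
  if (!is.null(schema)) sch[names(schema)] <- schema
  get <- function(f, default = NULL) {
    if (sch[[f]] %in% names(df)) df[[sch[[f]]]] else default
  }
  out <- data.frame(site_id = as.character(get("site_id")),
                    latitude = as.numeric(get("latitude")),
                    longitude = as.numeric(get("longitude")),
                    age_bp = as.numeric(get("age_bp")),
                    taxon = as.character(get("taxon")),
                    count = get("count"),
                    stringsAsFactors = FALSE)
  out$site_name <- as.character(get("site_name", out$site_id))
  out$elevation_m <- as.numeric(get("elevation_m", NA_real_))
  .check_counts(out$count, context = source)
  if (any(!is.finite(out$latitude)) || any(!is.finite(out$longitude)))
    stop(source, ": missing coordinates for some rows", call. = FALSE)
  if (any(out$age_bp < 0))
    warning(source, ": ", sum(out$age_bp < 0),
            " sample row(s) have negative (post-1950) ages", call. = FALSE)

  key <- paste(out$site_id, out$age_bp, out$taxon, sep = "\r")
  if (anyDuplicated(key)) {
    warning(source, ": summing counts over ",
            sum(duplicated(key)), " duplicated (site, age, taxon) row(s)",
            call. = FALSE)
    agg <- stats::aggregate(count ~ site_id + age_bp + taxon, data = out, FUN = sum)
    meta <- out[!duplicated(out$site_id),
                c("site_id", "site_name", "latitude", "longitude", "elevation_m")]
    out <- merge(agg, meta, by = "site_id", sort = FALSE)
  }

  seqs <- lapply(split(out, out$site_id), function(d) {
    pollen_sequence(site_id = d$site_id[1],
                    site_name = d$site_name[1],
                    latitude = d$latitude[1], longitude = d$longitude[1],
                    elevation_m = d$elevation_m[1],
                    samples = d[order(d$age_bp, d$taxon),
                                c("age_bp", "taxon", "count")])
  })
  seqs[order(names(seqs))]
}

#' Flatten pollen sequences back to a long table
#'
#' Inverse of [read_counts_long]: one row per (site, age, taxon).
#' `read -> write -> read` round-trips counts and metadata.
#'
#' @param seqs List of [pollen_sequence] objects.
#' @return Long-format data frame with the canonical columns.
#' @export
counts_to_long <- function(seqs) {
  do.call(rbind, lapply(unname(seqs), function(s) {
    data.frame(site_id = s$site_id, site_name = s$site_name,
               latitude = s$latitude, longitude = s$longitude,
               elevation_m = s$elevation_m,
               s$samples, stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Read a synonym / hierarchy table
#'
#' The table maps every original taxon name (as typed by an analyst) to
#' accepted names at three nested levels: H0 (most detailed accepted
#' pollen taxonomy), H1 (morphologically similar types combined, roughly
#' genus level) and H2 (coarse, readily identifiable morphological groups,
#' roughly family level), plus an inclusion flag restricting analyses to
#' terrestrial pollen and spores of vascular plants.
#'
#' The public synonym files in circulation do not share one column layout;
#' this package's own layout is columns `original`, `h0`, `h1`, `h2`,
#' `include`. The `include` column accepts logicals (`TRUE`/`FALSE`,
#' `1`/`0`, `yes`/`no`) or a habitat label, where `"terrestrial"` (and
#' `"include"`) mean included and any other label (e.g. `"aquatic"`)
#' means excluded.
#'
#' @param path CSV file path.
#' @return A validated `harmonisation_table` (see [harmonisation_table]).
#' @export
read_synonym_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("original", "h0", "h1", "h2", "include")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column '", miss[1], "' in ", path, call. = FALSE)
  df$include <- .parse_include(df$include, source = path)
  harmonisation_table(df)
}

.parse_include <- function(x, source = "table") {
  if (is.logical(x)) return(x)
  tok <- tolower(trimws(as.character(x)))
  inc <- tok %in% c("true", "t", "1", "yes", "y", "include", "included", "terrestrial")
  exc <- tok %in% c("false", "f", "0", "no", "n", "exclude", "excluded") |
    (!inc & nzchar(tok))
  if (any(!inc & !exc))
    stop(source, ": blank include flag", call. = FALSE)
  inc
}

#' Write a result table to CSV
#'
#' Plain CSV writer used for all result tables so outputs round-trip
#' losslessly through [utils::read.csv].
#'
#' @param table Data frame with named columns.
#' @param path Output file path.
#' @export
write_table <- function(table, path) {
  stopifnot(is.data.frame(table), !is.null(names(table)))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
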