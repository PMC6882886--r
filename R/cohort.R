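#' Region labels
#'
#' The five analysis regions, chosen to separate broad zones with distinct
#' climate and vegetation history while keeping subsets of similar size.
#' @export
REGIONS <- c("Boreal", "TemperateOceanic", "TemperateContinental",
             "MeridionalSubmeridional", "Alps")

#' Default region boundary parameters
#'
#' Study area: 25W--35E, north of 35N (bounds inclusive). Boreal is
#' latitude strictly above 57N; Meridional/Submeridional strictly south of
#' 45N; the Alps box (45--47N, 5--15E, inclusive) takes precedence; the
#' remaining Temperate belt splits into oceanic and continental at 11
#' degrees longitude (oceanic strictly west of the meridian).
#'
#' Note on the meridians: the temperate split and the Alps box only make
#' geographic sense in degrees East; values are exposed here so
#' sensitivity to every boundary can be tested.
#' @return Named list of boundary parameters (degrees).
#' @export
region_bounds <- function() {
  list(lon_min = -25, lon_max = 35, lat_min = 35,
       boreal_lat = 57, meridional_lat = 45,
       temperate_split_lon = 11,
       alps_lat = c(45, 47), alps_lon = c(5, 15))
}

#' Is a site inside the study area?
#'
#' @param lat,lon Coordinates in decimal degrees (vectorised).
#' @param bounds Boundary parameters, see [region_bounds].
#' @return Logical vector: `TRUE` iff `-25 <= lon <= 35` and `lat >= 35`
#'   (bounds inclusive).
#' @export
in_study_area <- function(lat, lon, bounds = region_bounds()) {
  lon >= bounds$lon_min & lon <= bounds$lon_max & lat >= bounds$lat_min
}

#' Assign a site to one of the five regions
#'
#' Total on the study area; the Alps box is evaluated first, then Boreal
#' (lat > 57), then Meridional/Submeridional (lat < 45), then the
#' oceanic/continental split of the Temperate belt.
#'
#' @inheritParams in_study_area
#' @return Factor with levels [REGIONS] (vectorised).
#' @export
assign_region <- function(lat, lon, bounds = region_bounds()) {
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  if (any(!in_study_area(lat, lon, bounds)))
    stop("coordinates outside the study area", call. = FALSE)
  out <- character(n)
  alps <- lat >= bounds$alps_lat[1] & lat <= bounds$alps_lat[2] &
    lon >= bounds$alps_lon[1] & lon <= bounds$alps_lon[2]
  out[alps] <- "Alps"
  out[!alps & lat > bounds$boreal_lat] <- "Boreal"
  out[!alps & lat <= bounds$boreal_lat & lat < bounds$meridional_lat] <-
    "MeridionalSubmeridional"
  temperate <- !nzchar(out)
  out[temperate & lon < bounds$temperate_split_lon] <- "TemperateOceanic"
  out[temperate & lon >= bounds$temperate_split_lon] <- "TemperateContinental"
  factor(out, levels = REGIONS)
}

#' Filter pollen sequences by identified-type count
#'
#' Sequences with very few identified types usually reflect diagrams with
#' limited identification of herbaceous pollen; they are removed by
#' requiring at least `min_types` distinct taxa (with positive counts)
#' over the whole sequence. The default of 32 corresponds to a minimum in
#' the frequency distribution of identified types per sequence and to the
#' average number of types in species-poor (boreal) samples.
#'
#' @param seqs List of [pollen_sequence] objects (already harmonised at
#'   the analysis level).
#' @param min_types Minimum distinct-taxon count (default 32).
#' @return List with `retained` (the surviving sequences) and `report`
#'   (data frame of site_id, n_types, retained flag for every input site).
#' @export
filter_sites <- function(seqs, min_types = 32) {
  n_types <- vapply(seqs, function(s)
    length(unique(s$samples$taxon[s$samples$count > 0])), 0L)
  report <- data.frame(site_id = vapply(seqs, `[[`, "", "site_id"),
                       n_types = n_types,
                       retained = n_types >= min_types,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(retained = seqs[report$retained], report = report)
}

#' Region of every site in a set
#'
#' @param seqs List of [pollen_sequence] objects.
#' @inheritParams in_study_area
#' @return Named factor, site_id -> region.
#' @export
site_regions <- function(seqs, bounds = region_bounds()) {
  lat <- vapply(seqs, `[[`, 0.0, "latitude")
  lon <- vapply(seqs, `[[`, 0.0, "longitude")
  reg <- assign_region(lat, lon, bounds)
  names(reg) <- vapply(seqs, `[[`, "", "site_id")
  reg
}
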