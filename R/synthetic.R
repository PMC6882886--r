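#' Configuration of the synthetic pollen-record generator
#'
#' The generator emulates the structure of a European-style multi-site,
#' multi-millennium pollen count database with known ground truth:
#' a built-in latitudinal richness gradient, time-varying evenness
#' (gradual forest closure in the north after the glacial, then
#' anthropogenic opening of the canopy in the late Holocene with the
#' arrival of archaeophytes), a small pool of prolific (tree) pollen
#' producers present nearly everywhere, skewed pollen productivity,
#' analyst-dependent naming noise resolved by the shipped synonym table,
#' and a constant long-distance background rain.
#'
#' The defaults define the study conditions every end-to-end check runs
#' under: forest closure ramps from 11.5 to 7 ka BP, canopy opening
#' starts at 3 ka BP, and the encoded strength of the latitudinal
#' gradient (types per degree latitude at the site-pool level) rises
#' from 0.45 in the Lateglacial to a first maximum of 1.2 at 7 ka,
#' relaxes slightly, and rises again after 3 ka.
#'
#' @param seed Integer seed; the same config is byte-reproducible.
#' @param n_sites_per_region Sites drawn uniformly within each region's
#'   bounds (default 25).
#' @param herb_pool_total Size of the continental herb taxon pool.
#' @param region_herb_pool Named per-region herb pool sizes (the
#'   Meridional pool is the richest by construction).
#' @param richness_base,richness_lat_scale Site herb-pool size is
#'   `richness_base - richness_lat_scale * s(t) * (lat - 35)`, where
#'   `s(t)` is the encoded slope schedule.
#' @param slope_lateglacial,closure_gain,closure_relax,opening_gain
#'   Parameters of the slope schedule `s(t)` (see [true_slope]).
#' @param forest_closure `c(start_ka, end_ka, dominance)`: window of the
#'   tree-mass ramp and the peak tree share of the pollen sum in
#'   northern regions.
#' @param opening_onset_ka Start of the anthropogenic opening (ka BP).
#' @param archaeophyte_count Taxa introduced after the opening onset.
#' @param productivity_skew Zipf exponent of the pollen-productivity
#'   distribution across taxa.
#' @param grains_per_sample `c(meanlog, sdlog)` of the lognormal grain
#'   total per raw sample.
#' @param samples_per_slice_mean Mean extra raw samples per site and
#'   millennium (`1 + rpois(.)` samples are drawn).
#' @param synonym_noise Probability that a site records a given herb
#'   taxon under a finer synonym name throughout (analyst habit).
#' @param pct_long_distance Fraction of every sample drawn from the
#'   continental mean composition (background rain).
#' @param aquatic_rate Probability a raw sample also contains aquatic
#'   taxa (excluded from the terrestrial sum by the synonym table).
#' @return List of class `generator_config`.
#' @export
generator_config <- function(seed = 42,
                             n_sites_per_region = 25,
                             herb_pool_total = 220,
                             region_herb_pool = c(
                               Boreal = 85,
                               TemperateOceanic = 130,
                               TemperateContinental = 120,
                               MeridionalSubmeridional = 170,
                               Alps = 120),
                             richness_base = 95,
                             richness_lat_scale = 1.8,
                             slope_lateglacial = 0.45,
                             closure_gain = 0.75,
                             closure_relax = 0.28,
                             opening_gain = 0.55,
                             forest_closure = c(start_ka = 11.5, end_ka = 7,
                                                dominance = 0.75),
                             opening_onset_ka = 3,
                             archaeophyte_count = 12,
                             productivity_skew = 1.0,
                             grains_per_sample = c(meanlog = log(1500),
                                                   sdlog = 0.5),
                             samples_per_slice_mean = 2,
                             synonym_noise = 0.15,
                             pct_long_distance = 0.05,
                             aquatic_rate = 0.3) {
  cfg <- as.list(environment())
  stopifnot(cfg$synonym_noise >= 0, cfg$synonym_noise <= 1,
            cfg$pct_long_distance >= 0, cfg$pct_long_distance <= 1,
            cfg$aquatic_rate >= 0, cfg$aquatic_rate <= 1,
            cfg$n_sites_per_region >= 1,
            all(cfg$region_herb_pool <= cfg$herb_pool_total))
  structure(cfg, class = "generator_config")
}

.tree_taxa <- function() c("Pinus", "Betula", "Quercus", "Alnus", "Corylus",
                           "Ulmus", "Tilia", "Fraxinus", "Picea", "Abies",
                           "Fagus", "Carpinus", "Salix", "Juniperus", "Populus")

.tree_families <- function() c(
  Pinus = "Pinaceae", Picea = "Pinaceae", Abies = "Pinaceae",
  Betula = "Betulaceae", Alnus = "Betulaceae", Corylus = "Betulaceae",
  Carpinus = "Betulaceae", Quercus = "Fagaceae", Fagus = "Fagaceae",
  Ulmus = "Ulmaceae", Tilia = "Malvaceae", Fraxinus = "Oleaceae",
  Salix = "Salicaceae", Populus = "Salicaceae", Juniperus = "Cupressaceae")

.aquatic_taxa <- function() c("Nymphaea", "Potamogeton", "Myriophyllum",
                              "Sparganium")

.herb_names <- function(k) sprintf("Herb%03d", k)
.arch_names <- function(k) sprintf("Archaeo%02d", k)

#' Forest-closure and canopy-opening fractions
#'
#' `closure_fraction` ramps 0 to 1 over the closure window and stays 1;
#' `opening_fraction` is 0 before the opening onset and ramps to 1 at
#' present. Vectorised over `t_ka` (thousands of years BP).
#'
#' @param t_ka Age in ka BP.
#' @param cfg A [generator_config].
#' @return Numeric in `[0, 1]`.
#' @export
closure_fraction <- function(t_ka, cfg) {
  start <- cfg$forest_closure[["start_ka"]]
  end <- cfg$forest_closure[["end_ka"]]
  pmin(pmax((start - t_ka) / (start - end), 0), 1)
}

#' @rdname closure_fraction
#' @export
opening_fraction <- function(t_ka, cfg) {
  on <- cfg$opening_onset_ka
  pmin(pmax((on - t_ka) / on, 0), 1)
}

#' Encoded latitudinal slope schedule (ground truth)
#'
#' The strength of the latitudinal gradient the generator builds in, in
#' site-pool types per degree latitude: a Lateglacial baseline, a rise to
#' a first maximum at the end of forest closure (northern site pools
#' shrink), a partial relaxation over the following three millennia, and
#' a second rise after the canopy opening. The pipeline's recovered
#' slope magnitude should track this schedule rank-for-rank.
#'
#' @inheritParams closure_fraction
#' @param slice_bp Slice centre in years BP (vectorised).
#' @return Slope magnitude (types per degree latitude, positive scale).
#' @export
true_slope <- function(slice_bp, cfg) {
  t_ka <- slice_bp / 1000
  end <- cfg$forest_closure[["end_ka"]]
  cl <- closure_fraction(t_ka, cfg)
  relax <- cfg$closure_relax * pmin(pmax((end - t_ka) / 3, 0), 1)
  cfg$slope_lateglacial + cfg$closure_gain * (cl - relax) +
    cfg$opening_gain * opening_fraction(t_ka, cfg)
}

# deterministic pools derived from the config seed
.generator_pools <- function(cfg) {
  withr_seed(cfg$seed, {
    herb_rank <- sample(cfg$herb_pool_total)
    herb_w <- stats::setNames(herb_rank^(-cfg$productivity_skew),
                              .herb_names(seq_len(cfg$herb_pool_total)))
    trees <- .tree_taxa()
    tree_w <- stats::setNames(seq_along(trees)^(-0.8), trees)
    region_pool <- lapply(cfg$region_herb_pool, function(k)
      sample(names(herb_w), k, prob = herb_w))
    arch <- .arch_names(seq_len(cfg$archaeophyte_count))
    arch_w <- stats::setNames(rev(seq_along(arch))^(-0.7), arch)
    list(herb_w = herb_w, tree_w = tree_w, region_pool = region_pool,
         arch = arch, arch_w = arch_w)
  })
}

# tree share of the pollen sum for a region at time t
.tree_dominance <- function(region, t_ka, cfg) {
  if (region == "MeridionalSubmeridional") return(0.45)
  d <- 0.35 + (cfg$forest_closure[["dominance"]] - 0.35) *
    closure_fraction(t_ka, cfg)
  if (region != "Boreal") d <- d - 0.2 * opening_fraction(t_ka, cfg)
  min(max(d, 0.05), 0.95)
}

#' Regional pollen composition at a time slice (generator truth)
#'
#' The expected regional composition the generator samples around: tree
#' taxa carry the (time-varying) dominance share, the region's herb pool
#' carries the rest with Zipf-skewed productivities, archaeophytes gain
#' mass after the opening onset, and a `pct_long_distance` fraction is
#' replaced by the continental mean composition. Sums to one.
#'
#' @param region One of [REGIONS].
#' @param slice_center_bp Slice centre in years BP.
#' @inheritParams closure_fraction
#' @return Named probability vector over taxa.
#' @export
composition <- function(region, slice_center_bp, cfg = generator_config()) {
  region <- match.arg(region, REGIONS)
  pools <- .generator_pools(cfg)
  .composition_from_pools(region, slice_center_bp, cfg, pools)
}

.composition_from_pools <- function(region, slice_center_bp, cfg, pools,
                                    herbs = NULL, trees = NULL, arch = NULL) {
  t_ka <- slice_center_bp / 1000
  d <- .tree_dominance(region, t_ka, cfg)
  if (is.null(herbs)) herbs <- pools$region_pool[[region]]
  if (is.null(trees)) trees <- names(pools$tree_w)
  op <- opening_fraction(t_ka, cfg)
  arch_share <- if (region == "Boreal") 0 else 0.05 * op
  if (is.null(arch)) arch <- if (arch_share > 0) pools$arch else character(0)
  if (arch_share == 0) arch <- character(0)
  tw <- pools$tree_w[trees]; tw <- tw / sum(tw) * d
  hw <- pools$herb_w[herbs]; hw <- hw / sum(hw) * (1 - d - arch_share)
  aw <- if (length(arch)) {
    v <- pools$arch_w[arch]; v / sum(v) * arch_share
  } else numeric(0)
  local <- c(tw, hw, aw)
  # continental background rain: prolific producers present nearly everywhere
  bg_herbs <- names(sort(pools$herb_w, decreasing = TRUE))[1:30]
  bg <- c(pools$tree_w / sum(pools$tree_w) * 0.8,
          stats::setNames(pools$herb_w[bg_herbs] / sum(pools$herb_w[bg_herbs]) * 0.2,
                          bg_herbs))
  all_tax <- union(names(local), names(bg))
  p <- stats::setNames(numeric(length(all_tax)), all_tax)
  p[names(local)] <- (1 - cfg$pct_long_distance) * local
  p[names(bg)] <- p[names(bg)] + cfg$pct_long_distance * bg
  p / sum(p)
}

# region bounding boxes used to place synthetic sites
.region_boxes <- function() list(
  Boreal = list(lat = c(57.1, 70), lon = c(5, 35)),
  TemperateOceanic = list(lat = c(45, 56.9), lon = c(-10, 10.9)),
  TemperateContinental = list(lat = c(45, 56.9), lon = c(11.1, 35)),
  MeridionalSubmeridional = list(lat = c(35, 44.9), lon = c(-10, 35)),
  Alps = list(lat = c(45.1, 46.9), lon = c(5.1, 14.9)))

#' Synonym / hierarchy table covering every name the generator can emit
#'
#' Trees map to themselves at H0/H1 and to family groups at H2; herbs and
#' archaeophytes are grouped pairwise at H1 and four-wise at H2; finer
#' "agg." variant names map back to their parent; aquatic taxa carry
#' `include = FALSE`.
#'
#' @inheritParams closure_fraction
#' @return A [harmonisation_table].
#' @export
generator_synonyms <- function(cfg = generator_config()) {
  trees <- .tree_taxa()
  fam <- .tree_families()
  herbs <- .herb_names(seq_len(cfg$herb_pool_total))
  arch <- .arch_names(seq_len(cfg$archaeophyte_count))
  base <- rbind(
    data.frame(original = trees, h0 = trees, h1 = trees,
               h2 = unname(fam[trees]), include = TRUE),
    data.frame(original = herbs, h0 = herbs,
               h1 = sprintf("HerbG1_%03d", ceiling(seq_along(herbs) / 2)),
               h2 = sprintf("HerbG2_%03d", ceiling(seq_along(herbs) / 4)),
               include = TRUE),
    data.frame(original = arch, h0 = arch,
               h1 = sprintf("ArchG1_%02d", ceiling(seq_along(arch) / 2)),
               h2 = sprintf("ArchG2_%02d", ceiling(seq_along(arch) / 4)),
               include = TRUE),
    data.frame(original = .aquatic_taxa(), h0 = .aquatic_taxa(),
               h1 = .aquatic_taxa(), h2 = .aquatic_taxa(), include = FALSE))
  variants <- base[base$include, ]
  variants$original <- paste(variants$original, "agg.")
  harmonisation_table(rbind(base, variants))
}

#' Generate a full synthetic dataset with ground truth
#'
#' Places `n_sites_per_region` sites uniformly within each region's
#' bounds, draws per-site, per-slice raw samples (ages uniform within the
#' millennial window, grain totals lognormal) multinomially from the
#' site's composition, and emits some taxa under finer synonym names that
#' the shipped table resolves. The site composition realises the
#' latitudinal gradient: a site's herb pool is the first
#' `richness_base - richness_lat_scale * s(t) * (lat - 35)` taxa of its
#' site-specific priority ordering of the regional pool, so pool richness
#' declines with latitude at the encoded, time-varying rate `s(t)`.
#'
#' @inheritParams closure_fraction
#' @return List: `counts` (long-format data frame accepted by
#'   [counts_from_columns]), `synonyms` (the [harmonisation_table]),
#'   `sites` (site metadata with regions), and `truth` (slope schedule
#'   per slice, dominance schedule, pool sizes, opening onset and
#'   archaeophyte arrival slice) — everything needed to score pipeline
#'   output against what was encoded.
#' @export
generate_dataset <- function(cfg = generator_config()) {
  pools <- .generator_pools(cfg)
  boxes <- .region_boxes()
  slices <- slice_centres()
  synonyms <- generator_synonyms(cfg)
  aquatics <- .aquatic_taxa()
  withr_seed(cfg$seed + 1L, {
    sites <- do.call(rbind, lapply(REGIONS, function(rg) {
      b <- boxes[[rg]]
      data.frame(site_id = sprintf("%s_%02d", abbreviate(rg, 4),
                                   seq_len(cfg$n_sites_per_region)),
                 region = rg,
                 latitude = round(stats::runif(cfg$n_sites_per_region,
                                               b$lat[1], b$lat[2]), 3),
                 longitude = round(stats::runif(cfg$n_sites_per_region,
                                                b$lon[1], b$lon[2]), 3),
                 stringsAsFactors = FALSE)
    }))
    rows <- vector("list", nrow(sites) * length(slices))
    k <- 0L
    for (i in seq_len(nrow(sites))) {
      rg <- sites$region[i]
      lat <- sites$latitude[i]
      pool <- pools$region_pool[[rg]]
      priority <- sample(pool)                     # site-specific ordering
      my_trees <- sample(names(pools$tree_w), 10)
      my_arch <- sample(pools$arch, min(8, length(pools$arch)))
      finer <- names(pools$herb_w)[stats::runif(cfg$herb_pool_total) <
                                     cfg$synonym_noise]
      for (sl in slices) {
        s_t <- true_slope(sl, cfg)
        n_herb <- round(cfg$richness_base -
                          cfg$richness_lat_scale * s_t * (lat - 35))
        n_herb <- min(max(n_herb, 12L), length(priority))
        p <- .composition_from_pools(rg, sl, cfg, pools,
                                     herbs = priority[seq_len(n_herb)],
                                     trees = my_trees, arch = my_arch)
        n_samp <- 1L + stats::rpois(1, cfg$samples_per_slice_mean - 1)
        ages <- sort(stats::runif(n_samp, sl - 500, sl + 500))
        ages <- pmax(ages, 0)                      # no post-1950 ages
        ages <- unique(round(ages, 1))
        for (age in ages) {
          grains <- max(50L, round(stats::rlnorm(
            1, cfg$grains_per_sample[["meanlog"]],
            cfg$grains_per_sample[["sdlog"]])))
          cnt <- stats::rmultinom(1, grains, p)[, 1]
          cnt <- cnt[cnt > 0]
          nm <- names(cnt)
          recode <- nm %in% finer
          nm[recode] <- paste(nm[recode], "agg.")
          if (stats::runif(1) < cfg$aquatic_rate) {
            aq <- sample(aquatics, 1 + stats::rbinom(1, 1, 0.5))
            aq_cnt <- 1 + stats::rpois(length(aq), 4)
            nm <- c(nm, aq)
            cnt <- c(cnt, aq_cnt)
          }
          k <- k + 1L
          rows[[k]] <- data.frame(site_id = sites$site_id[i],
                                  latitude = lat,
                                  longitude = sites$longitude[i],
                                  age_bp = age, taxon = nm,
                                  count = as.integer(cnt),
                                  stringsAsFactors = FALSE)
        }
      }
    }
    counts <- do.call(rbind, rows[seq_len(k)])
    truth <- list(
      slope_schedule = data.frame(slice_center_bp = slices,
                                  true_slope = true_slope(slices, cfg)),
      dominance = do.call(rbind, lapply(REGIONS, function(rg)
        data.frame(region = rg, slice_center_bp = slices,
                   tree_dominance = vapply(slices / 1000, function(t)
                     .tree_dominance(rg, t, cfg), 0.0)))),
      region_pool_sizes = vapply(pools$region_pool, length, 0L),
      opening_onset_ka = cfg$opening_onset_ka,
      # first slice centre strictly younger than the onset
      archaeophyte_arrival_bp = 1000 * ceiling(cfg$opening_onset_ka - 1),
      closure_window_ka = cfg$forest_closure[c("start_ka", "end_ka")])
    list(counts = counts, synonyms = synonyms, sites = sites, truth = truth)
  })
}

#' Write a generated dataset to CSV files
#'
#' @param dataset Output of [generate_dataset].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`counts.csv`, `synonyms.csv`,
#'   `sites.csv`).
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.csv"),
             synonyms = file.path(dir, "synonyms.csv"),
             sites = file.path(dir, "sites.csv"))
  write_table(dataset$counts, paths["counts"])
  write_table(as.data.frame(dataset$synonyms), paths["synonyms"])
  write_table(dataset$sites, paths["sites"])
  invisible(paths)
}

#' A deterministic hand-checkable fixture
#'
#' Four sites (two Boreal, two Meridional), three slices (0, 1000,
#' 2000 BP with sample ages at the slice centres), ten original names
#' collapsing to eight accepted H0 taxa (two "-type" synonyms). All
#' counts are literal so every downstream number can be verified by hand.
#'
#' @return List: `seqs` (named list of [pollen_sequence]), `synonyms`
#'   (a [harmonisation_table]), `counts` (the long table), and
#'   `total_grains` (the fixed known grain total, 1700).
#' @export
small_fixture <- function() {
  syn <- harmonisation_table(data.frame(
    original = c("Pinus", "Betula", "Quercus", "Poaceae", "Artemisia",
                 "Plantago", "Cichorioideae", "Ephedra",
                 "Plantago lanceolata-type", "Poaceae (wild)"),
    h0 = c("Pinus", "Betula", "Quercus", "Poaceae", "Artemisia",
           "Plantago", "Cichorioideae", "Ephedra", "Plantago", "Poaceae"),
    h1 = c("Pinus", "Betula", "Quercus", "Poaceae", "Asteraceae-group",
           "Plantago", "Asteraceae-group", "Ephedra", "Plantago", "Poaceae"),
    h2 = c("Pinaceae", "Betulaceae", "Fagaceae", "Poaceae", "Asteraceae",
           "Plantaginaceae", "Asteraceae", "Ephedraceae", "Plantaginaceae",
           "Poaceae"),
    include = TRUE))
  row <- function(site, age, taxon, count)
    data.frame(age_bp = age, taxon = taxon, count = count,
               stringsAsFactors = FALSE)
  s <- list(
    pollen_sequence("BOR_1", 60, 20, rbind(
      row("BOR_1", 0,    c("Pinus", "Betula", "Poaceae"), c(120, 60, 20)),
      row("BOR_1", 1000, c("Pinus", "Betula", "Artemisia"), c(100, 70, 10)),
      row("BOR_1", 2000, c("Pinus", "Betula"), c(110, 50)))),
    pollen_sequence("BOR_2", 62, 25, rbind(
      row("BOR_2", 0,    c("Pinus", "Betula", "Poaceae (wild)"), c(90, 40, 15)),
      row("BOR_2", 1000, c("Pinus", "Betula"), c(95, 45)),
      row("BOR_2", 2000, c("Pinus", "Betula", "Ephedra"), c(80, 40, 5)))),
    pollen_sequence("MER_1", 38, 10, rbind(
      row("MER_1", 0,    c("Quercus", "Poaceae", "Plantago", "Cichorioideae"),
          c(60, 50, 20, 15)),
      row("MER_1", 1000, c("Quercus", "Poaceae", "Plantago lanceolata-type"),
          c(70, 40, 10)),
      row("MER_1", 2000, c("Quercus", "Poaceae", "Artemisia"), c(65, 45, 20)))),
    pollen_sequence("MER_2", 40, 5, rbind(
      row("MER_2", 0,    c("Quercus", "Poaceae", "Artemisia", "Ephedra"),
          c(55, 45, 25, 10)),
      row("MER_2", 1000, c("Quercus", "Cichorioideae", "Plantago"),
          c(75, 20, 15)),
      row("MER_2", 2000, c("Quercus", "Poaceae"), c(70, 40)))))
  names(s) <- vapply(s, `[[`, "", "site_id")
  list(seqs = s, synonyms = syn, counts = counts_to_long(s),
       total_grains = 1700L)
}
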