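# Seeded generator of synthetic plant-frugivore datasets with the
# statistical structure the pipeline assumes: nested ecoregion-within-biome
# species pools, spatial distance decay, human-disturbance filtering,
# log-normal interaction weights and effort-driven detection.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a landscape of 3 latitudinal biomes each split into 3
#' ecoregions, 4 sites per ecoregion (36 networks), regional pools drawn
#' from 240 plants and 200 birds, moderate cross-boundary turnover, spatial
#' distance decay on a ~3000 km scale, disturbance filtering of a
#' synanthropic species subset, log-normal weights and study-level sampling
#' covariates.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param n_biomes,ecoregions_per_biome,sites_per_ecoregion Landscape shape.
#' @param plant_pool,bird_pool Global pool sizes.
#' @param biome_pool_overlap,ecoregion_pool_overlap Probability that a
#'   species is shared across biome (resp. ecoregion) pools rather than
#'   exclusive to its home region.
#' @param distance_decay_rate Occupancy decay with distance from a species'
#'   range centre, per km.
#' @param boundary_effect Occupancy penalty per boundary crossed (0 = none):
#'   shared species occur at rate `(1 - boundary_effect)^crossings` away
#'   from their home region.
#' @param disturbance_effect Strength of human-footprint filtering of
#'   sensitive vs synanthropic species.
#' @param weight_lognormal_sigma sdlog of the interaction weights.
#' @param detection_effort_range Range (hours) of per-study sampling effort.
#' @param n_studies Number of studies sites are grouped into.
#' @param placement `"confounded"` (regions are geographic blocks) or
#'   `"randomized"` (region labels shuffled across sites, making the
#'   boundary term orthogonal to space).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_biomes = 3L, ecoregions_per_biome = 3L,
                       sites_per_ecoregion = 4L, plant_pool = 240L,
                       bird_pool = 200L, biome_pool_overlap = 0.4,
                       ecoregion_pool_overlap = 0.5,
                       distance_decay_rate = 3e-4,
                       boundary_effect = 0.3, disturbance_effect = 1,
                       weight_lognormal_sigma = 1,
                       detection_effort_range = c(20, 200),
                       n_studies = 8L,
                       placement = c("confounded", "randomized")) {
  placement <- match.arg(placement)
  cfg <- list(seed = as.integer(seed), n_biomes = as.integer(n_biomes),
              ecoregions_per_biome = as.integer(ecoregions_per_biome),
              sites_per_ecoregion = as.integer(sites_per_ecoregion),
              plant_pool = as.integer(plant_pool),
              bird_pool = as.integer(bird_pool),
              biome_pool_overlap = biome_pool_overlap,
              ecoregion_pool_overlap = ecoregion_pool_overlap,
              distance_decay_rate = distance_decay_rate,
              boundary_effect = boundary_effect,
              disturbance_effect = disturbance_effect,
              weight_lognormal_sigma = weight_lognormal_sigma,
              detection_effort_range = detection_effort_range,
              n_studies = as.integer(n_studies),
              placement = placement)
  stopifnot(cfg$n_biomes >= 1, cfg$ecoregions_per_biome >= 1,
            cfg$sites_per_ecoregion >= 1,
            cfg$biome_pool_overlap >= 0, cfg$biome_pool_overlap <= 1,
            cfg$ecoregion_pool_overlap >= 0,
            cfg$ecoregion_pool_overlap <= 1,
            cfg$distance_decay_rate >= 0, cfg$disturbance_effect >= 0,
            cfg$weight_lognormal_sigma >= 0)
  structure(cfg, class = "sim_config")
}

#' Simulate site metadata on a structured landscape
#'
#' Biomes are latitudinal bands (60 S to 60 N), ecoregions contiguous
#' longitude blocks within a band, sites uniform within their ecoregion
#' cell (or, under `placement = "randomized"`, region labels are shuffled
#' across sites). Human footprint is a low/high mixture independent of
#' region; elevation follows a latitudinal gradient plus noise; sampling
#' covariates and method descriptors are drawn per study, with studies
#' grouping geographically proximate sites.
#'
#' @param config A [sim_config()].
#' @return A site-metadata data frame passing [check_metadata()].
#' @export
simulate_landscape <- function(config) {
  n_sites <- config$n_biomes * config$ecoregions_per_biome *
    config$sites_per_ecoregion
  if (n_sites == 0L) stop("zero sites requested", call. = FALSE)
  with_seed(config$seed, {
    lat_breaks <- seq(-60, 60, length.out = config$n_biomes + 1)
    lon_breaks <- seq(-150, 150,
                      length.out = config$ecoregions_per_biome + 1)
    rows <- list()
    idx <- 0L
    for (b in seq_len(config$n_biomes)) {
      for (e in seq_len(config$ecoregions_per_biome)) {
        for (s in seq_len(config$sites_per_ecoregion)) {
          idx <- idx + 1L
          rows[[idx]] <- data.frame(
            network_id = sprintf("net%03d", idx),
            ecoregion_id = sprintf("E%d_%d", b, e),
            biome_id = sprintf("B%d", b),
            latitude = stats::runif(1, lat_breaks[b], lat_breaks[b + 1]),
            longitude = stats::runif(1, lon_breaks[e], lon_breaks[e + 1]),
            stringsAsFactors = FALSE)
        }
      }
    }
    md <- do.call(rbind, rows)
    if (config$placement == "randomized") {
      shuffle <- sample.int(n_sites)
      md$ecoregion_id <- md$ecoregion_id[shuffle]
      md$biome_id <- md$biome_id[shuffle]
    }
    # disturbance: low/high mixture, independent of region
    high <- stats::runif(n_sites) < 0.5
    md$human_footprint <- ifelse(high, stats::runif(n_sites, 25, 45),
                                 stats::runif(n_sites, 0, 10))
    md$elevation <- pmax(0, 1500 - 15 * abs(md$latitude) +
                           stats::rnorm(n_sites, 0, 300))
    # studies group geographically proximate sites
    k <- min(config$n_studies, n_sites)
    cl <- if (k >= n_sites) seq_len(n_sites) else
      stats::kmeans(cbind(md$latitude, md$longitude), centers = k,
                    nstart = 5)$cluster
    md$study_id <- sprintf("study%02d", cl)
    hours <- stats::runif(k, config$detection_effort_range[1],
                          config$detection_effort_range[2])
    months <- sample(1:12, k, replace = TRUE)
    years <- stats::runif(k, 1990, 2020)
    intensity <- stats::runif(k, 0.2, 1)
    designs <- sample(c("transect", "plot", "focal"), k, replace = TRUE)
    focus <- sample(c("phytocentric", "zoocentric"), k, replace = TRUE)
    ftype <- sample(c("visits", "fruits_eaten"), k, replace = TRUE)
    cover <- sample(c("total", "partial"), k, replace = TRUE)
    md$sampling_hours <- hours[cl]
    md$sampling_months <- months[cl]
    md$sampling_year_mean <- years[cl]
    md$sampling_intensity <- intensity[cl]
    md$method_design <- designs[cl]
    md$method_focus <- focus[cl]
    md$method_frequency_type <- ftype[cl]
    md$method_coverage <- cover[cl]
    rownames(md) <- NULL
    check_metadata(md)
  })
}

#' Simulate local networks for a landscape
#'
#' Species are assigned home ecoregions (hence biomes), range centres,
#' exclusivity levels derived from the pool-overlap parameters, a
#' synanthropy class, and a latent matching trait. A species occupies a
#' site with probability `p0 * exp(-decay * d(site, range centre)) *
#' (1 - boundary_effect)^crossings * disturbance_filter`; exclusive species
#' never leave their home region. Links among co-occurring species follow a
#' fixed global trait-matching web, are thinned by an effort-driven
#' detection probability, and carry log-normal weights.
#'
#' @param metadata Output of [simulate_landscape()].
#' @param config The same [sim_config()].
#' @return List of `interaction_matrix` objects, one per metadata row, each
#'   passing [validate_network()] at defaults.
#' @export
simulate_networks <- function(metadata, config) {
  with_seed(config$seed + 1L, {
    pool <- draw_species_pool(metadata, config)
    nets <- vector("list", nrow(metadata))
    for (i in seq_len(nrow(metadata))) {
      nets[[i]] <- draw_site_network(metadata[i, ], pool, config)
    }
    nets
  })
}

# global species pool with regional structure and a trait-matching web
draw_species_pool <- function(metadata, config) {
  ecos <- unique(metadata$ecoregion_id)
  eco_biome <- metadata$biome_id[match(ecos, metadata$ecoregion_id)]
  # region centroids for range centres
  cen_lat <- tapply(metadata$latitude, metadata$ecoregion_id, mean)[ecos]
  cen_lon <- tapply(metadata$longitude, metadata$ecoregion_id, mean)[ecos]
  draw_guild <- function(n, prefix) {
    home <- sample(seq_along(ecos), n, replace = TRUE)
    # exclusivity: ecoregion-exclusive, biome-exclusive, or cosmopolitan
    u <- stats::runif(n)
    level <- ifelse(u < 1 - config$ecoregion_pool_overlap, "ecoregion",
                    ifelse(u < 1 - config$ecoregion_pool_overlap *
                             config$biome_pool_overlap, "biome", "global"))
    data.frame(
      id = sprintf("%s%04d", prefix, seq_len(n)),
      home_eco = ecos[home],
      home_biome = eco_biome[home],
      level = level,
      range_lat = unname(cen_lat[home]) + stats::rnorm(n, 0, 3),
      range_lon = unname(cen_lon[home]) + stats::rnorm(n, 0, 3),
      synanthropic = stats::runif(n) < 0.2,
      trait = stats::runif(n),
      stringsAsFactors = FALSE)
  }
  plants <- draw_guild(config$plant_pool, "P")
  birds <- draw_guild(config$bird_pool, "B")
  # fixed global web: link possible when traits match closely enough
  eta <- exp(-((outer(plants$trait, birds$trait, "-")) / 0.35)^2)
  possible <- matrix(stats::runif(length(eta)) < 0.85 * eta, nrow(eta))
  list(plants = plants, birds = birds, possible = possible)
}

occupancy_prob <- function(sp, site, config, p0 = 0.8) {
  d_km <- geosphere::distHaversine(
    cbind(sp$range_lon, sp$range_lat),
    c(site$longitude, site$latitude), r = .earth_radius_km)
  crossings <- (sp$home_eco != site$ecoregion_id) +
    (sp$home_biome != site$biome_id)
  allowed <- ifelse(sp$level == "ecoregion",
                    sp$home_eco == site$ecoregion_id,
                    ifelse(sp$level == "biome",
                           sp$home_biome == site$biome_id, TRUE))
  fp <- site$human_footprint / 50
  # disturbance filtering is compositional: the filter is normalised by its
  # pool mean so synanthropes replace sensitive species at disturbed sites
  # rather than thinning the community
  filt <- ifelse(sp$synanthropic,
                 exp(-config$disturbance_effect * (1 - fp)),
                 exp(-config$disturbance_effect * fp))
  if (mean(filt) > 0) filt <- filt / mean(filt)
  pmin(1, p0 * exp(-config$distance_decay_rate * d_km) *
         (1 - config$boundary_effect)^crossings * filt) * allowed
}

draw_site_network <- function(site, pool, config, max_tries = 10L) {
  pp <- occupancy_prob(pool$plants, site, config)
  pb <- occupancy_prob(pool$birds, site, config)
  p_detect <- 1 - exp(-site$sampling_hours / 60)
  for (try in seq_len(max_tries)) {
    occ_p <- which(stats::runif(length(pp)) < pp)
    occ_b <- which(stats::runif(length(pb)) < pb)
    if (length(occ_p) < 3L || length(occ_b) < 3L) next
    links <- pool$possible[occ_p, occ_b, drop = FALSE] &
      matrix(stats::runif(length(occ_p) * length(occ_b)) < p_detect,
             length(occ_p))
    if (sum(links) == 0L) next
    w <- matrix(0, length(occ_p), length(occ_b),
                dimnames = list(pool$plants$id[occ_p],
                                pool$birds$id[occ_b]))
    w[links] <- ceiling(stats::rlnorm(sum(links), meanlog = 1,
                                      sdlog = config$weight_lognormal_sigma))
    net <- tryCatch(
      drop_zero_margins(interaction_matrix(w, site$network_id)),
      error = function(e) NULL)
    if (!is.null(net) && validate_network(net)$passed) return(net)
  }
  stop("could not realise a valid network for site ", site$network_id,
       " after ", max_tries, " draws (pools too small or rates too low)",
       call. = FALSE)
}

#' Simulate a full synthetic dataset
#'
#' Composes [simulate_landscape()] and [simulate_networks()] and returns
#' networks, metadata, and the generating truth. Optionally writes the
#' bundle to disk (network CSVs, metadata CSV, truth JSON).
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory to write a fixture bundle into.
#' @return A `synthetic_dataset` list: `networks`, `metadata`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  metadata <- simulate_landscape(config)
  networks <- simulate_networks(metadata, config)
  out <- structure(list(networks = networks, metadata = metadata,
                        truth = unclass(config)),
                   class = "synthetic_dataset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "networks"), showWarnings = FALSE)
    for (net in networks) {
      write_network(net, file.path(out_dir, "networks",
                                   paste0(network_id(net), ".csv")))
    }
    utils::write.csv(metadata, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset: %d networks, %d ecoregions, %d biomes (seed %d)>\n",
    length(x$networks), length(unique(x$metadata$ecoregion_id)),
    length(unique(x$metadata$biome_id)), x$truth$seed))
  invisible(x)
}
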