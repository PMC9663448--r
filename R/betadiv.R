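#' Sorensen dissimilarity between two finite sets
#'
#' The Whittaker/Sorensen-family dissimilarity `(b + c) / (2a + b + c)`,
#' with `a` the shared elements, `b` those unique to `set_a` and `c` those
#' unique to `set_b`. Undefined (NA, with warning) when both sets are empty.
#'
#' @param set_a,set_b Character vectors treated as sets.
#' @return Dissimilarity in \[0, 1\], or `NA`.
#' @export
sorensen_dissimilarity <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) == 0L && length(set_b) == 0L) {
    warning("both sets empty; Sorensen dissimilarity undefined",
            call. = FALSE)
    return(NA_real_)
  }
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  cc <- length(setdiff(set_b, set_a))
  (b + cc) / (2 * a + b + cc)
}

# guild-tagged species set: a plant and a bird sharing a name never collide
species_set <- function(net) {
  c(paste0("P::", plant_ids(net)), paste0("B::", bird_ids(net)))
}

# binarized link set as "plant||bird" keys
link_set <- function(net) {
  idx <- which(unclass(net) > 0, arr.ind = TRUE)
  paste0(plant_ids(net)[idx[, 1]], "||", bird_ids(net)[idx[, 2]])
}

#' Species turnover between two networks (beta_S)
#'
#' Sorensen dissimilarity over the pooled species sets of the two networks
#' (plants and birds pooled, guild-tagged).
#'
#' @param net_a,net_b Cleaned `interaction_matrix` objects.
#' @return Dissimilarity in \[0, 1\].
#' @export
species_beta <- function(net_a, net_b) {
  sorensen_dissimilarity(species_set(net_a), species_set(net_b))
}

#' Interaction dissimilarity between two networks (beta_WN)
#'
#' Sorensen dissimilarity over the binarized link sets of the whole
#' networks: a link is a (plant, bird) pair with positive weight.
#'
#' @inheritParams species_beta
#' @return Dissimilarity in \[0, 1\].
#' @export
interaction_beta <- function(net_a, net_b) {
  sorensen_dissimilarity(link_set(net_a), link_set(net_b))
}

#' Interaction rewiring between two networks (beta_OS)
#'
#' Restricts both networks to the subweb of shared plants x shared birds and
#' takes the Sorensen dissimilarity of the two subweb link sets: the extent
#' to which shared species interact differently. Undefined (`NA`) when no
#' plant or no bird is shared, or when both subwebs are linkless.
#'
#' @inheritParams species_beta
#' @return Dissimilarity in \[0, 1\], or `NA` where undefined.
#' @export
rewiring_beta <- function(net_a, net_b) {
  sp <- intersect(plant_ids(net_a), plant_ids(net_b))
  sb <- intersect(bird_ids(net_a), bird_ids(net_b))
  if (length(sp) == 0L || length(sb) == 0L) return(NA_real_)
  sub_a <- unclass(net_a)[sp, sb, drop = FALSE]
  sub_b <- unclass(net_b)[sp, sb, drop = FALSE]
  la <- which(sub_a > 0)
  lb <- which(sub_b > 0)
  if (length(la) == 0L && length(lb) == 0L) return(NA_real_)
  a <- length(intersect(la, lb))
  b <- length(setdiff(la, lb))
  cc <- length(setdiff(lb, la))
  (b + cc) / (2 * a + b + cc)
}

#' Full beta-diversity partition for one pair of networks
#'
#' Computes species turnover (beta_S), whole-network interaction
#' dissimilarity (beta_WN), rewiring of shared species (beta_OS, `NA` where
#' undefined), the species-turnover component `beta_ST = beta_WN - beta_OS`,
#' and the underlying link/species sharing counts.
#'
#' @inheritParams species_beta
#' @return A one-row data frame.
#' @export
beta_partition <- function(net_a, net_b) {
  la <- link_set(net_a)
  lb <- link_set(net_b)
  shared <- length(intersect(la, lb))
  os <- rewiring_beta(net_a, net_b)
  wn <- interaction_beta(net_a, net_b)
  data.frame(
    id_a = network_id(net_a), id_b = network_id(net_b),
    beta_s = species_beta(net_a, net_b),
    beta_wn = wn,
    beta_os = os,
    beta_st = if (is.na(os)) NA_real_ else wn - os,
    shared_links = shared,
    unique_links_a = length(la) - shared,
    unique_links_b = length(lb) - shared,
    shared_plants = length(intersect(plant_ids(net_a), plant_ids(net_b))),
    shared_birds = length(intersect(bird_ids(net_a), bird_ids(net_b))),
    stringsAsFactors = FALSE)
}

#' Pairwise beta-diversity distance matrix
#'
#' @param nets List of `interaction_matrix` objects with unique ids.
#' @param which `"species"` (beta_S) or `"interaction"` (beta_WN).
#' @return A `dist_matrix` over networks with values in \[0, 1\].
#' @export
pairwise_beta <- function(nets, which = c("species", "interaction")) {
  which <- match.arg(which)
  ids <- vapply(nets, network_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate network ids", call. = FALSE)
  if (length(nets) < 2L) stop("need at least two networks", call. = FALSE)
  sets <- if (which == "species") lapply(nets, species_set)
          else lapply(nets, link_set)
  n <- length(nets)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- sorensen_dissimilarity(sets[[i]], sets[[j]])
    }
  }
  dist_matrix(d, labels = ids)
}

#' Network pairs with defined rewiring, plus covariate distances
#'
#' Enumerates all unordered network pairs, keeps those for which beta_OS is
#' defined (shared plants and birds with at least one subweb link), and
#' attaches the same pairwise predictor distances used by the main models:
#' boundary indicators, footprint/elevational/sampling absolute differences
#' and the great-circle distance.
#'
#' @param nets List of `interaction_matrix` objects.
#' @param metadata Site-metadata data frame covering all networks (see
#'   [read_metadata()]); may be `NULL` to return beta values only.
#' @return Data frame, one row per retained pair. Empty (with a warning)
#'   when no pair shares species of both guilds.
#' @export
shared_pairs_subset <- function(nets, metadata = NULL) {
  ids <- vapply(nets, network_id, character(1))
  rows <- list()
  n <- length(nets)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, n)) {
      p <- beta_partition(nets[[i]], nets[[j]])
      if (!is.na(p$beta_os)) rows[[length(rows) + 1L]] <- p
    }
  }
  if (length(rows) == 0L) {
    warning("no network pair with defined rewiring", call. = FALSE)
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  if (!is.null(metadata)) {
    md <- metadata[match(ids, metadata$network_id), ]
    ia <- match(out$id_a, ids)
    ib <- match(out$id_b, ids)
    out$same_ecoregion <- as.integer(md$ecoregion_id[ia] ==
                                       md$ecoregion_id[ib])
    out$same_biome <- as.integer(md$biome_id[ia] == md$biome_id[ib])
    out$disturbance_distance <- abs(md$human_footprint[ia] -
                                      md$human_footprint[ib])
    out$elevation_distance <- abs(md$elevation[ia] - md$elevation[ib])
    hv <- haversine_distance(md[, c("network_id", "latitude", "longitude")])
    out$spatial_distance <- unclass(hv)[cbind(ia, ib)]
    for (col in c("sampling_hours", "sampling_months", "sampling_year_mean",
                  "sampling_intensity")) {
      if (col %in% names(md)) {
        out[[paste0(sub("sampling_", "", col), "_distance")]] <-
          abs(md[[col]][ia] - md[[col]][ib])
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a long-format pair table of beta-diversity values
#'
#' @param nets List of `interaction_matrix` objects.
#' @param path TSV output path.
#' @return The pair table, invisibly.
#' @export
write_beta_pairs <- function(nets, path) {
  n <- length(nets)
  rows <- list()
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, n)) {
      rows[[length(rows) + 1L]] <- beta_partition(nets[[i]], nets[[j]])
    }
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}
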