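#' Construct a weighted bipartite interaction matrix
#'
#' An `interaction_matrix` holds one local network: a labelled, nonnegative
#' plants-by-birds matrix of interaction frequencies (e.g. fruit-feeding
#' events). Rows are the lower trophic level (plants), columns the upper
#' (frugivorous birds).
#'
#' @param weights Numeric matrix of nonnegative, finite interaction
#'   frequencies. Row and column names are used as species ids unless
#'   `plant_ids`/`bird_ids` are given.
#' @param network_id Character scalar identifying the network.
#' @param plant_ids,bird_ids Optional character vectors of species ids;
#'   default to `rownames(weights)` and `colnames(weights)`.
#' @return An object of class `interaction_matrix`: the weight matrix with a
#'   `network_id` attribute.
#' @examples
#' m <- matrix(c(1, 0, 0, 2), 2, 2,
#'             dimnames = list(c("p1", "p2"), c("b1", "b2")))
#' net <- interaction_matrix(m, "net1")
#' n_plants(net)
#' @export
interaction_matrix <- function(weights, network_id = "network",
                               plant_ids = rownames(weights),
                               bird_ids = colnames(weights)) {
  weights <- as.matrix(weights)
  if (!is.numeric(weights)) {
    stop("interaction weights must be numeric", call. = FALSE)
  }
  if (is.null(plant_ids) || is.null(bird_ids)) {
    stop("plant and bird ids are required (set dimnames or pass explicitly)",
         call. = FALSE)
  }
  plant_ids <- as.character(plant_ids)
  bird_ids <- as.character(bird_ids)
  if (length(plant_ids) != nrow(weights) || length(bird_ids) != ncol(weights)) {
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(plant_ids)) {
    stop("duplicate plant id: ",
         paste(unique(plant_ids[duplicated(plant_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(bird_ids)) {
    stop("duplicate bird id: ",
         paste(unique(bird_ids[duplicated(bird_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(weights))) {
    stop("all interaction weights must be finite", call. = FALSE)
  }
  if (any(weights < 0)) {
    bad <- which(weights < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative weight at plant '%s', bird '%s'",
                 plant_ids[bad[1]], bird_ids[bad[2]]), call. = FALSE)
  }
  if (!any(weights > 0)) {
    stop("network has no positive interaction weight", call. = FALSE)
  }
  dimnames(weights) <- list(plant_ids, bird_ids)
  structure(weights, network_id = as.character(network_id),
            class = c("interaction_matrix", "matrix", "array"))
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix '%s': %d plants x %d birds, %d links>\n",
              network_id(x), nrow(x), ncol(x), n_links(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Accessors for interaction matrices
#'
#' @param net An `interaction_matrix`.
#' @return `network_id()` the network id; `plant_ids()`/`bird_ids()` the
#'   species labels; `n_plants()`/`n_birds()` guild sizes; `n_links()` the
#'   number of strictly positive cells.
#' @export
network_id <- function(net) attr(net, "network_id")

#' @rdname network_id
#' @export
plant_ids <- function(net) rownames(net)

#' @rdname network_id
#' @export
bird_ids <- function(net) colnames(net)

#' @rdname network_id
#' @export
n_plants <- function(net) nrow(net)

#' @rdname network_id
#' @export
n_birds <- function(net) ncol(net)

#' @rdname network_id
#' @export
n_links <- function(net) sum(net > 0)

#' Read a weighted bipartite network from a delimited file
#'
#' Expected layout: first row holds bird ids, first column plant ids, body
#' numeric nonnegative weights. Zero rows/columns are retained; use
#' [drop_zero_margins()] to clean.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"tsv"`. Guessed from the extension by default.
#' @param network_id Id for the resulting network; defaults to the file name
#'   without extension.
#' @return An [interaction_matrix()].
#' @export
read_network <- function(path, dialect = c("guess", "csv", "tsv"),
                         network_id = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "guess") {
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE))
      "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  if (ncol(raw) < 2) stop("network file needs at least one bird column",
                          call. = FALSE)
  plants <- raw[[1]]
  birds <- colnames(raw)[-1]
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell '%s' at plant '%s', bird '%s' in %s",
                 body[bad[1], bad[2]], plants[bad[1]], birds[bad[2]], path),
         call. = FALSE)
  }
  if (is.null(network_id)) {
    network_id <- sub("\\.[^.]+$", "", basename(path))
  }
  interaction_matrix(num, network_id = network_id,
                     plant_ids = plants, bird_ids = birds)
}

#' Write a network to a delimited file
#'
#' Inverse of [read_network()]: cell values and label order round-trip
#' exactly.
#'
#' @param net An `interaction_matrix`.
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_network <- function(net, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(plant = plant_ids(net), unclass(net),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- ""
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Remove all-zero rows and columns from a network
#'
#' Idempotent; retained weights are unchanged.
#'
#' @param net An `interaction_matrix`.
#' @return The cleaned `interaction_matrix`.
#' @export
drop_zero_margins <- function(net) {
  keep_r <- rowSums(net) > 0
  keep_c <- colSums(net) > 0
  if (!any(keep_r) || !any(keep_c)) {
    stop("empty network: no species left in a guild after cleaning",
         call. = FALSE)
  }
  interaction_matrix(unclass(net)[keep_r, keep_c, drop = FALSE],
                     network_id = network_id(net))
}

#' Validate a network against dataset inclusion criteria
#'
#' A network is retained when each trophic level has at least
#' `min_species_per_guild` species (default 3, i.e. "more than two species
#' per level") and the total species count strictly exceeds
#' `min_total_species`. The latter defaults to 0 and can be raised (e.g. to
#' 10) to reproduce the small-network sensitivity filter.
#'
#' @param net An `interaction_matrix` (cleaned).
#' @param min_species_per_guild Minimum species per guild (inclusive).
#' @param min_total_species Total species must strictly exceed this.
#' @return A `validation_report`: list with `network_id`, `passed`,
#'   `reasons`, `n_plants`, `n_birds`, `n_links`.
#' @export
validate_network <- function(net, min_species_per_guild = 3,
                             min_total_species = 0) {
  reasons <- character(0)
  np <- n_plants(net); nb <- n_birds(net)
  if (np < min_species_per_guild) {
    reasons <- c(reasons, sprintf(
      "plant guild has %d species (< %d required)", np,
      min_species_per_guild))
  }
  if (nb < min_species_per_guild) {
    reasons <- c(reasons, sprintf(
      "bird guild has %d species (< %d required)", nb,
      min_species_per_guild))
  }
  if ((np + nb) <= min_total_species) {
    reasons <- c(reasons, sprintf(
      "total species %d does not exceed %d", np + nb, min_total_species))
  }
  structure(list(network_id = network_id(net),
                 passed = length(reasons) == 0L,
                 reasons = reasons,
                 n_plants = np, n_birds = nb, n_links = n_links(net)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report '%s': %s>\n", x$network_id,
              if (x$passed) "passed" else "FAILED"))
  if (!x$passed) cat(paste0("  - ", x$reasons, collapse = "\n"), "\n")
  invisible(x)
}

#' Tabulate validation reports
#'
#' @param reports A list of `validation_report` objects.
#' @return A data frame, one row per network; `reasons` collapsed with "; ".
#' @export
validation_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(network_id = r$network_id, passed = r$passed,
               n_plants = r$n_plants, n_birds = r$n_birds,
               n_links = r$n_links,
               reasons = paste(r$reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  }))
}

# columns a metadata table must carry; sampling columns may be NA-flagged
.metadata_required <- c("network_id", "study_id", "latitude", "longitude",
                        "elevation", "ecoregion_id", "biome_id",
                        "human_footprint")
.metadata_sampling <- c("sampling_hours", "sampling_months",
                        "sampling_year_mean", "sampling_intensity",
                        "method_design", "method_focus",
                        "method_frequency_type", "method_coverage")

#' Read and check a site-metadata table
#'
#' Reads a CSV of per-network covariates (coordinates, elevation,
#' ecoregion/biome membership, human footprint, sampling effort and method
#' descriptors, study id) and enforces the structural invariants: unique
#' network ids, coordinates in range, and ecoregions nested within biomes
#' (each ecoregion maps to exactly one biome).
#'
#' @param path CSV path with a header matching the metadata field names.
#' @return A data frame of site metadata.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_metadata(md)
}

#' @rdname read_metadata
#' @param metadata A metadata data frame to check in place.
#' @export
check_metadata <- function(metadata) {
  missing_req <- setdiff(.metadata_required, names(metadata))
  if (length(missing_req)) {
    stop("metadata missing required columns: ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  missing_samp <- setdiff(.metadata_sampling, names(metadata))
  if (length(missing_samp)) {
    warning("metadata missing sampling columns (flagged as NA): ",
            paste(missing_samp, collapse = ", "), call. = FALSE)
    for (col in missing_samp) metadata[[col]] <- NA
  }
  if (anyDuplicated(metadata$network_id)) {
    stop("duplicate network_id in metadata: ",
         paste(unique(metadata$network_id[duplicated(metadata$network_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(metadata$latitude < -90 | metadata$latitude > 90, na.rm = TRUE)) {
    stop("latitude out of [-90, 90] for network(s): ",
         paste(metadata$network_id[
           which(metadata$latitude < -90 | metadata$latitude > 90)],
           collapse = ", "), call. = FALSE)
  }
  if (any(metadata$longitude < -180 | metadata$longitude > 180,
          na.rm = TRUE)) {
    stop("longitude out of [-180, 180] for network(s): ",
         paste(metadata$network_id[
           which(metadata$longitude < -180 | metadata$longitude > 180)],
           collapse = ", "), call. = FALSE)
  }
  # nesting: one biome per ecoregion
  map <- unique(metadata[, c("ecoregion_id", "biome_id")])
  dup <- map$ecoregion_id[duplicated(map$ecoregion_id)]
  if (length(dup)) {
    rows <- map[map$ecoregion_id %in% dup, ]
    stop("ecoregion(s) mapped to multiple biomes: ",
         paste(sprintf("%s->%s", rows$ecoregion_id, rows$biome_id),
               collapse = ", "), call. = FALSE)
  }
  metadata
}

#' Ratio of observed to regionally known interactions
#'
#' A raw sampling-completeness metric: the number of links in the local
#' network divided by the number of interactions known regionally among the
#' species present in that network. The regional catalogue is restricted to
#' pairs whose plant and bird both occur in the network before counting.
#'
#' @param net An `interaction_matrix`.
#' @param regional_catalog Data frame with columns `plant` and `bird`
#'   listing known possible interactions for the region.
#' @return A single ratio; `NA` (with a warning) when the catalogue lists no
#'   pair among the network's species.
#' @export
ratio_of_interactions <- function(net, regional_catalog) {
  stopifnot(all(c("plant", "bird") %in% names(regional_catalog)))
  cat_pairs <- unique(regional_catalog[
    regional_catalog$plant %in% plant_ids(net) &
      regional_catalog$bird %in% bird_ids(net), c("plant", "bird")])
  if (nrow(cat_pairs) == 0L) {
    warning("no catalogue pair among the network's species; ",
            "ratio of interactions undefined", call. = FALSE)
    return(NA_real_)
  }
  n_links(net) / nrow(cat_pairs)
}
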