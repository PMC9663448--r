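# End-to-end orchestration: matrices -> models -> partition -> outputs.

#' Build the standard predictor and response matrices for a dataset
#'
#' The canonical recipe behind the main models: binary ecoregion and biome
#' membership matrices, absolute-difference matrices for human footprint,
#' elevation and the sampling covariates, the Haversine spatial matrix, the
#' Gower/PCoA methods matrix, the two beta-diversity responses and the
#' PCA-composite structural dissimilarity.
#'
#' @param nets List of `interaction_matrix` objects.
#' @param metadata Site metadata covering the networks.
#' @param seed Seed for the modularity search inside the structural
#'   profiles.
#' @param structural Compute the structural response too (default TRUE;
#'   skipping it is faster for models that do not need it).
#' @return Named list of `dist_matrix` objects.
#' @export
build_distance_matrices <- function(nets, metadata, seed = 1L,
                                    structural = TRUE) {
  ids <- vapply(nets, network_id, character(1))
  md <- metadata[match(ids, metadata$network_id), ]
  if (anyNA(md$network_id)) {
    stop("metadata missing for network(s): ",
         paste(ids[is.na(md$network_id)], collapse = ", "), call. = FALSE)
  }
  named <- function(col) stats::setNames(md[[col]], ids)
  out <- list(
    ecoregion = binary_membership_distance(named("ecoregion_id")),
    biome = binary_membership_distance(named("biome_id")),
    disturbance = absolute_difference_distance(named("human_footprint")),
    spatial = haversine_distance(
      md[, c("network_id", "latitude", "longitude")]),
    elevation = absolute_difference_distance(named("elevation")),
    hours = absolute_difference_distance(named("sampling_hours")),
    months = absolute_difference_distance(named("sampling_months")),
    years = absolute_difference_distance(named("sampling_year_mean")),
    intensity = absolute_difference_distance(named("sampling_intensity")),
    methods = methods_distance(
      md[, c("network_id", "method_design", "method_focus",
             "method_frequency_type", "method_coverage")]),
    beta_s = pairwise_beta(nets, "species"),
    beta_wn = pairwise_beta(nets, "interaction"))
  if (structural) {
    out$structural <- structural_dissimilarity(
      structural_profiles(nets, seed = seed))
  }
  out
}

#' Default model specifications for the three responses
#'
#' Mirrors the main model structure: binary ecoregion and biome boundary
#' indicators as parametric terms; human disturbance, spatial, elevational
#' and the sampling distances as spline smooths.
#'
#' @param response One of `"beta_s"`, `"beta_wn"`, `"structural"`.
#' @param n_perm,seed,basis_dim Passed to [model_spec()].
#' @return A [model_spec()].
#' @export
default_model_spec <- function(response = c("beta_wn", "beta_s",
                                            "structural"),
                               n_perm = 1000L, seed = 1L, basis_dim = 10L) {
  response <- match.arg(response)
  model_spec(response,
             parametric_terms = c("ecoregion", "biome"),
             smooth_terms = c("disturbance", "spatial", "elevation",
                              "hours", "months", "years", "intensity",
                              "methods"),
             basis_dim = basis_dim, n_perm = n_perm, seed = seed)
}

#' Run the full boundary-analysis pipeline
#'
#' Validates and cleans the networks, builds all distance matrices, fits a
#' GAM-MRM per requested response, runs deviance partitioning over the
#' variables of interest, exports the rewiring pair table, optionally
#' jackknifes by study, and writes a result bundle (tables, JSON, manifest)
#' when `out_dir` is given. Identical inputs and seed give identical
#' outputs.
#'
#' @param nets List of `interaction_matrix` objects, or a directory of
#'   network CSVs.
#' @param metadata Metadata data frame or CSV path.
#' @param responses Responses to model.
#' @param n_perm Permutations per model.
#' @param seed Master seed.
#' @param variables_of_interest Terms partitioned in the deviance analysis.
#' @param jackknife Run the by-study jackknife (slower).
#' @param fast_perm Reuse observed smoothing parameters in permutation
#'   refits.
#' @param out_dir Optional output directory.
#' @param min_species_per_guild,min_total_species Inclusion filters.
#' @return A `pipeline_result` list: `models`, `partitions`, `rewiring`,
#'   `validation`, optional `jackknife`, and a `manifest`.
#' @export
run_pipeline <- function(nets, metadata,
                         responses = c("beta_s", "beta_wn", "structural"),
                         n_perm = 199L, seed = 1L,
                         variables_of_interest = c("ecoregion", "biome",
                                                   "spatial",
                                                   "disturbance"),
                         jackknife = FALSE, fast_perm = FALSE,
                         out_dir = NULL, min_species_per_guild = 3,
                         min_total_species = 0) {
  if (is.character(nets)) {
    paths <- list.files(nets, pattern = "\\.(csv|tsv)$", full.names = TRUE)
    nets <- lapply(paths, read_network)
  }
  if (is.character(metadata)) metadata <- read_metadata(metadata)

  nets <- lapply(nets, drop_zero_margins)
  reports <- lapply(nets, validate_network,
                    min_species_per_guild = min_species_per_guild,
                    min_total_species = min_total_species)
  passed <- vapply(reports, `[[`, logical(1), "passed")
  if (!all(passed)) {
    warning(sum(!passed), " network(s) failed validation and were dropped",
            call. = FALSE)
  }
  nets <- nets[passed]
  if (length(nets) < 4L) stop("fewer than 4 valid networks", call. = FALSE)

  data <- build_distance_matrices(nets, metadata, seed = seed,
                                  structural = "structural" %in% responses)
  models <- list()
  partitions <- list()
  for (resp in responses) {
    spec <- default_model_spec(resp, n_perm = n_perm, seed = seed)
    # drop constant predictors (e.g. single-region landscapes)
    spec <- prune_constant_terms(spec, data)
    models[[resp]] <- gam_mrm(data, spec, fast_perm = fast_perm)
    voi <- intersect(variables_of_interest,
                     c(spec$parametric_terms, spec$smooth_terms))
    partitions[[resp]] <- deviance_partition(data, spec, voi)
  }
  rewiring <- suppressWarnings(shared_pairs_subset(nets, metadata))
  jk <- NULL
  if (jackknife) {
    spec_jk <- default_model_spec(responses[1], n_perm = 0L, seed = seed)
    jk <- jackknife_by_study(
      nets, metadata,
      function(n, m) build_distance_matrices(
        n, m, seed = seed, structural = responses[1] == "structural"),
      spec_jk)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("netbounds")),
    r_version = R.version.string,
    seed = seed, n_perm = n_perm,
    n_networks = length(nets),
    responses = responses,
    variables_of_interest = variables_of_interest,
    timestamp = NULL)
  out <- structure(list(models = models, partitions = partitions,
                        rewiring = rewiring,
                        validation = validation_table(reports),
                        jackknife = jk, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_bundle(out, out_dir)
  out
}

# drop model terms whose vectorized distances are constant
prune_constant_terms <- function(spec, data) {
  keep_ok <- function(nm) {
    v <- vectorize_lower_triangle(data[[nm]])$values
    if (length(unique(v)) < 2L) {
      warning("dropping constant term '", nm, "'", call. = FALSE)
      FALSE
    } else TRUE
  }
  spec$parametric_terms <-
    Filter(keep_ok, spec$parametric_terms)
  spec$smooth_terms <- Filter(keep_ok, spec$smooth_terms)
  spec
}

write_pipeline_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (resp in names(result$models)) {
    result_table(result$models[[resp]],
                 file.path(out_dir, paste0("model_", resp, ".tsv")))
    m <- result$models[[resp]]
    jsonlite::write_json(
      list(parametric = m$parametric, smooths = m$smooths,
           deviance_explained = m$deviance_explained,
           n_pairs = m$n_pairs, n_perm = m$n_perm, seed = m$seed),
      file.path(out_dir, paste0("model_", resp, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    p <- result$partitions[[resp]]
    jsonlite::write_json(
      list(components = p$components, residual = p$residual,
           full_deviance = p$full_deviance,
           controls_deviance = p$controls_deviance),
      file.path(out_dir, paste0("partition_", resp, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (nrow(result$rewiring)) {
    utils::write.table(result$rewiring,
                       file.path(out_dir, "rewiring_pairs.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(result$validation,
                     file.path(out_dir, "validation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(result$jackknife)) {
    utils::write.table(result$jackknife,
                       file.path(out_dir, "jackknife.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %d model(s) on %d networks>\n",
              length(x$models), x$manifest$n_networks))
  for (resp in names(x$models)) {
    cat("\n== response:", resp, "==\n")
    print(x$models[[resp]])
  }
  invisible(x)
}
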