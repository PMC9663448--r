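#' Labelled symmetric dissimilarity matrix
#'
#' The universal currency of the pipeline: a symmetric, zero-diagonal,
#' nonnegative matrix of pairwise dissimilarities between labelled units
#' (networks or regions). `kind = "binary"` matrices contain only 0/1
#' (boundary membership); everything else is `"quantitative"`.
#'
#' @param values Square numeric matrix; symmetry is checked to 1e-12 and the
#'   matrix is symmetrised by averaging.
#' @param labels Unit labels; default `rownames(values)`.
#' @param kind `"quantitative"` or `"binary"`.
#' @return A `dist_matrix` object.
#' @export
dist_matrix <- function(values, labels = rownames(values),
                        kind = c("quantitative", "binary")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("dist_matrix must be square", call. = FALSE)
  }
  if (is.null(labels)) stop("dist_matrix needs labels", call. = FALSE)
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate labels", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite dissimilarity", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-12) {
    stop("matrix not symmetric (tolerance 1e-12)", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  if (any(diag(values) != 0)) stop("nonzero diagonal", call. = FALSE)
  if (any(values < 0)) stop("negative dissimilarity", call. = FALSE)
  if (kind == "binary" && !all(values %in% c(0, 1))) {
    stop("binary dist_matrix must contain only 0/1", call. = FALSE)
  }
  dimnames(values) <- list(labels, labels)
  structure(values, kind = kind, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix (%s): %d units>\n", attr(x, "kind"), nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' @rdname dist_matrix
#' @param x A `dist_matrix`.
#' @export
dm_labels <- function(x) rownames(x)

#' @rdname dist_matrix
#' @export
dm_kind <- function(x) attr(x, "kind")

#' Write/read a dist_matrix as square CSV (labels as header and first column)
#' @param x A `dist_matrix`.
#' @param path File path.
#' @export
write_dist_matrix <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @param kind Kind of the matrix being read.
#' @export
read_dist_matrix <- function(path, kind = "quantitative") {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  dist_matrix(m, kind = kind)
}

#' Binary boundary membership distance
#'
#' Pairs of networks in the same region (ecoregion or biome) get
#' dissimilarity 0, pairs in distinct regions 1.
#'
#' @param memberships Named character vector: `network_id -> region_id`.
#' @return A binary `dist_matrix` over networks.
#' @export
binary_membership_distance <- function(memberships) {
  if (is.null(names(memberships)) || any(!nzchar(names(memberships)))) {
    stop("memberships must be a named vector (network ids)", call. = FALSE)
  }
  if (anyNA(memberships)) {
    stop("missing region label for network(s): ",
         paste(names(memberships)[is.na(memberships)], collapse = ", "),
         call. = FALSE)
  }
  d <- outer(memberships, memberships, FUN = "!=") * 1
  diag(d) <- 0
  dist_matrix(d, labels = names(memberships), kind = "binary")
}

#' Environmental dissimilarity between regions via PCA
#'
#' Z-scores the environmental columns, runs a PCA, retains the smallest
#' number of leading components reaching `variance_target` (or exactly
#' `n_components`), and returns the Euclidean distance between the retained
#' score vectors.
#'
#' @param env Data frame with a `region_id` column and numeric environmental
#'   columns (e.g. mean annual temperature, temperature seasonality, mean
#'   annual rainfall, rainfall seasonality, slope, human footprint).
#' @param variance_target Fraction of variance the retained components must
#'   reach (default 0.85). Ignored when `n_components` is given.
#' @param n_components Exact number of components to retain (optional).
#' @return A `dist_matrix` over regions.
#' @export
environmental_distance <- function(env, variance_target = 0.85,
                                   n_components = NULL) {
  stopifnot("region_id" %in% names(env))
  if (anyDuplicated(env$region_id)) stop("one row per region required",
                                         call. = FALSE)
  x <- as.matrix(env[, setdiff(names(env), "region_id"), drop = FALSE])
  if (!is.numeric(x)) stop("environmental columns must be numeric",
                           call. = FALSE)
  rownames(x) <- env$region_id
  pca_score_distance(x, variance_target, n_components)
}

# shared PCA -> Euclidean-distance core (used for environment and structure)
pca_score_distance <- function(x, variance_target, n_components) {
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) == 0L) stop("all columns constant; no variation to analyse",
                          call. = FALSE)
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  cumvar <- cumsum(p$sdev^2) / sum(p$sdev^2)
  if (is.null(n_components)) {
    k <- which(cumvar >= variance_target - 1e-12)[1]
  } else {
    if (n_components > ncol(p$x)) {
      stop(sprintf("requested %d components but only %d available",
                   n_components, ncol(p$x)), call. = FALSE)
    }
    k <- n_components
  }
  scores <- p$x[, seq_len(k), drop = FALSE]
  d <- as.matrix(stats::dist(scores))
  out <- dist_matrix(d, labels = rownames(x))
  attr(out, "n_components") <- k
  attr(out, "variance_explained") <- cumvar[k]
  out
}

#' Expand a region-level distance matrix to network level
#'
#' `d(net_i, net_j)` becomes the dissimilarity of the regions the two
#' networks sit in; same-region pairs get 0.
#'
#' @param region_dist A `dist_matrix` over regions.
#' @param memberships Named character vector `network_id -> region_id`.
#' @return A `dist_matrix` over networks.
#' @export
expand_to_networks <- function(region_dist, memberships) {
  missing <- setdiff(unique(memberships), dm_labels(region_dist))
  if (length(missing)) {
    stop("region(s) absent from region_dist: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- match(memberships, dm_labels(region_dist))
  d <- unclass(region_dist)[idx, idx, drop = FALSE]
  diag(d) <- 0
  dist_matrix(d, labels = names(memberships), kind = dm_kind(region_dist))
}

#' Absolute-difference (1-D Euclidean) distance
#'
#' Pairwise `|v_i - v_j|` over a per-network scalar covariate (human
#' footprint, elevation, sampling hours/months/years/intensity). Networks
#' with a missing value are excluded with a warning.
#'
#' @param values Named numeric vector `network_id -> value`.
#' @return A `dist_matrix` over the networks with non-missing values.
#' @export
absolute_difference_distance <- function(values) {
  if (is.null(names(values))) stop("values must be named by network id",
                                   call. = FALSE)
  if (anyNA(values)) {
    warning("excluding network(s) with missing value: ",
            paste(names(values)[is.na(values)], collapse = ", "),
            call. = FALSE)
    values <- values[!is.na(values)]
  }
  d <- abs(outer(values, values, "-"))
  dist_matrix(d, labels = names(values))
}

# IUGG mean Earth radius, km
.earth_radius_km <- 6371.0088

#' Great-circle (Haversine) distance between network sites
#'
#' @param coords Data frame with columns `network_id`, `latitude`,
#'   `longitude` (decimal degrees), or a 2-column lat/lon matrix with
#'   rownames.
#' @return A `dist_matrix` of distances in kilometres (Earth radius
#'   6371.0088 km).
#' @export
haversine_distance <- function(coords) {
  if (is.data.frame(coords)) {
    stopifnot(all(c("network_id", "latitude", "longitude") %in% names(coords)))
    ids <- coords$network_id
    lat <- coords$latitude
    lon <- coords$longitude
  } else {
    ids <- rownames(coords)
    lat <- coords[, 1]
    lon <- coords[, 2]
  }
  if (any(abs(lat) > 90) || any(abs(lon) > 180) || anyNA(lat) || anyNA(lon)) {
    stop("invalid coordinate(s)", call. = FALSE)
  }
  p <- cbind(lon, lat)
  d <- geosphere::distm(p, fun = function(a, b) {
    geosphere::distHaversine(a, b, r = .earth_radius_km)
  })
  diag(d) <- 0
  dist_matrix(d, labels = ids)
}

#' Gower distance over mixed categorical/quantitative columns
#'
#' Per-variable distances (categorical: 0/1 mismatch; quantitative:
#' range-normalised absolute difference) averaged with equal weights.
#' Constant quantitative columns are dropped with a warning.
#'
#' @param table Data frame; character/factor columns are treated as
#'   categorical, numeric columns as quantitative. An optional `network_id`
#'   column provides labels (else rownames).
#' @return A `dist_matrix` with values in \[0, 1\].
#' @export
gower_mixed_distance <- function(table) {
  labels <- if ("network_id" %in% names(table)) {
    l <- as.character(table$network_id)
    table$network_id <- NULL
    l
  } else if (!is.null(rownames(table))) rownames(table) else
    as.character(seq_len(nrow(table)))
  if (ncol(table) == 0L) stop("no variables to compare", call. = FALSE)
  n <- nrow(table)
  acc <- matrix(0, n, n)
  used <- 0L
  for (col in names(table)) {
    v <- table[[col]]
    if (is.numeric(v)) {
      rng <- diff(range(v))
      if (rng == 0) {
        warning("dropping constant quantitative column: ", col,
                call. = FALSE)
        next
      }
      acc <- acc + abs(outer(v, v, "-")) / rng
    } else {
      v <- as.character(v)
      acc <- acc + (outer(v, v, "!=") * 1)
    }
    used <- used + 1L
  }
  if (used == 0L) stop("all columns dropped; nothing to compare",
                       call. = FALSE)
  d <- acc / used
  diag(d) <- 0
  dist_matrix(d, labels = labels)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres the squared dissimilarities, eigendecomposes, and returns
#' coordinates on the leading `n_axes` axes (ordered by eigenvalue).
#' Negative eigenvalues are discarded; their share of total absolute inertia
#' is reported via a message and stored as an attribute.
#'
#' @param dist A `dist_matrix`.
#' @param n_axes Number of axes to keep; must not exceed the number of
#'   positive eigenvalues.
#' @return Numeric matrix (units x axes) with rownames, plus attributes
#'   `eigenvalues` and `negative_inertia`.
#' @export
pcoa <- function(dist, n_axes) {
  d <- unclass(dist)
  n <- nrow(d)
  b <- -0.5 * d^2
  b <- sweep(b, 1, rowMeans(b))
  b <- sweep(b, 2, colMeans(b))  # second sweep also removes the grand mean
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-9
  pos <- eg$values > tol
  inertia <- sum(abs(eg$values))
  neg_share <- if (inertia == 0) 0 else
    sum(abs(pmin(eg$values, 0))) / inertia
  if (neg_share > 1e-8) {
    message(sprintf(
      "pcoa: discarding negative eigenvalues (%.2f%% of absolute inertia)",
      100 * neg_share))
  }
  if (sum(pos) == 0L) {
    # all points coincide: every axis is degenerate, coordinates all zero
    coords <- matrix(0, n, n_axes,
                     dimnames = list(dm_labels(dist),
                                     paste0("axis", seq_len(n_axes))))
    attr(coords, "eigenvalues") <- eg$values
    attr(coords, "negative_inertia") <- neg_share
    return(coords)
  }
  if (n_axes > sum(pos)) {
    stop(sprintf("n_axes = %d exceeds the %d positive eigenvalues",
                 n_axes, sum(pos)), call. = FALSE)
  }
  keep <- which(pos)[seq_len(n_axes)]
  coords <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eg$values[keep]), n_axes)
  rownames(coords) <- dm_labels(dist)
  colnames(coords) <- paste0("axis", seq_len(n_axes))
  attr(coords, "eigenvalues") <- eg$values
  attr(coords, "negative_inertia") <- neg_share
  coords
}

#' Sampling-methods dissimilarity
#'
#' Combines the categorical method descriptors (design, focus, interaction
#' frequency type, coverage) into one distance: Gower distance over the
#' method columns, PCoA, then Euclidean distance on the retained axes.
#'
#' @param methods Data frame with a `network_id` column and the method
#'   columns.
#' @param n_axes Number of PCoA axes to retain (default 4, capped at the
#'   number of positive eigenvalues).
#' @return A `dist_matrix` over networks.
#' @export
methods_distance <- function(methods, n_axes = 4) {
  g <- gower_mixed_distance(methods)
  coords <- suppressMessages(pcoa_safe(g, n_axes))
  d <- as.matrix(stats::dist(coords))
  dist_matrix(d, labels = rownames(coords))
}

# pcoa with n_axes capped at the positive-eigenvalue count
pcoa_safe <- function(dist, n_axes) {
  d <- unclass(dist)
  b <- -0.5 * d^2
  b <- sweep(b, 1, rowMeans(b))
  b <- sweep(b, 2, colMeans(b))
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-9
  npos <- sum(eg$values > tol)
  pcoa(dist, max(1L, min(n_axes, npos)))
}

#' Vectorize the lower triangle of a distance matrix
#'
#' Unravels the unique unordered pairs of a `dist_matrix` in a fixed order
#' (pairs `(i, j)` with `i < j` over sorted labels by default), the common
#' design-row order shared by all matrices entering a model.
#'
#' @param dist A `dist_matrix`.
#' @param label_order Label order defining the pair sequence; default
#'   `sort(dm_labels(dist))`.
#' @return List with `values` (length n(n-1)/2) and `pairs` (data frame
#'   `id_a`, `id_b`).
#' @export
vectorize_lower_triangle <- function(dist,
                                     label_order = sort(dm_labels(dist))) {
  if (!setequal(label_order, dm_labels(dist)) ||
      length(label_order) != length(dm_labels(dist))) {
    stop("label_order does not match matrix labels", call. = FALSE)
  }
  m <- unclass(dist)[label_order, label_order, drop = FALSE]
  n <- length(label_order)
  idx <- which(upper.tri(m), arr.ind = TRUE)       # pairs i < j
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  list(values = m[idx],
       pairs = data.frame(id_a = label_order[idx[, 1]],
                          id_b = label_order[idx[, 2]],
                          stringsAsFactors = FALSE))
}

#' Rebuild a distance matrix from a vectorized lower triangle
#'
#' @param values Vector from [vectorize_lower_triangle()].
#' @param pairs Matching pair index data frame.
#' @param kind Matrix kind.
#' @return A `dist_matrix`.
#' @export
devectorize <- function(values, pairs, kind = "quantitative") {
  labels <- sort(unique(c(pairs$id_a, pairs$id_b)))
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  ia <- match(pairs$id_a, labels)
  ib <- match(pairs$id_b, labels)
  m[cbind(ia, ib)] <- values
  m[cbind(ib, ia)] <- values
  dist_matrix(m, labels = labels, kind = kind)
}
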