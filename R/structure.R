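#' Weighted connectance
#'
#' Shannon-entropy-based weighted linkage density divided by total species
#' count. With marginal totals `r_i` (plants), `c_j` (birds), grand total
#' `F`, and `H` the entropy of a row/column weight distribution (base 2 by
#' default, giving `2^H` "effective partners"),
#' `LDw = 1/2 * (sum_i r_i/F * 2^(H_i) + sum_j c_j/F * 2^(H_j))` and
#' connectance is `LDw / (n_plants + n_birds)`. Higher values indicate lower
#' network-level specialization.
#'
#' @param net A cleaned `interaction_matrix` with positive total weight.
#' @param base Logarithm base for the entropy (default 2).
#' @return Weighted connectance in (0, 1\].
#' @export
weighted_connectance <- function(net, base = 2) {
  w <- unclass(net)
  f <- sum(w)
  if (f <= 0) stop("total interaction weight is zero", call. = FALSE)
  eff <- function(x) {                 # effective partners: base^H
    p <- x[x > 0] / sum(x)
    base^(-sum(p * log(p, base = base)))
  }
  ld <- 0.5 * (sum(rowSums(w) / f * apply(w, 1, eff)) +
               sum(colSums(w) / f * apply(w, 2, eff)))
  ld / (nrow(w) + ncol(w))
}

#' Weighted nestedness by overlap and decreasing fill (wNODF)
#'
#' For each ordered row pair (i above j): if row i's marginal total is
#' strictly greater than row j's and row i's fill (number of positive cells)
#' is at least row j's, the pair contributes 100 times the fraction of row
#' j's positive cells whose weight is strictly below row i's weight in the
#' same column; otherwise it contributes 0. Columns are treated
#' symmetrically. wNODF is the mean contribution over all row and column
#' pairs, on a 0-100 scale.
#'
#' @param net An `interaction_matrix` with at least 2 rows and 2 columns.
#' @return wNODF in \[0, 100\].
#' @export
wnodf <- function(net) {
  w <- unclass(net)
  if (nrow(w) < 2 || ncol(w) < 2) {
    stop("wNODF needs at least 2 rows and 2 columns", call. = FALSE)
  }
  s <- wnodf_pairs(w) + wnodf_pairs(t(w))
  npairs <- choose(nrow(w), 2) + choose(ncol(w), 2)
  unname(s / npairs)
}

# sum of paired contributions over unordered row pairs of m; the row with
# the strictly larger marginal total plays the "upper" role (equivalent to
# pre-sorting rows by decreasing totals), so the metric is invariant to
# label permutation
wnodf_pairs <- function(m) {
  tot <- rowSums(m)
  fill <- rowSums(m > 0)
  s <- 0
  n <- nrow(m)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (tot[i] == tot[j]) next
      hi <- if (tot[i] > tot[j]) i else j
      lo <- i + j - hi
      if (fill[hi] >= fill[lo] && fill[lo] > 0) {
        s <- s + 100 * sum(m[lo, ] > 0 & m[lo, ] < m[hi, ]) / fill[lo]
      }
    }
  }
  s
}

#' Interaction evenness
#'
#' Shannon evenness applied to the interaction weight distribution:
#' `-sum(p_ij log p_ij) / log(R * C)` with `p_ij = w_ij / F` and `R x C` the
#' matrix dimensions (the "prod" denominator convention); zero cells
#' contribute nothing. A single-cell network is defined as 0.
#'
#' @param net An `interaction_matrix` with positive total weight.
#' @return Evenness in \[0, 1\].
#' @export
interaction_evenness <- function(net) {
  w <- unclass(net)
  f <- sum(w)
  if (f <= 0) stop("total interaction weight is zero", call. = FALSE)
  ncells <- length(w)
  if (ncells == 1L) return(0)
  p <- w[w > 0] / f
  -sum(p * log(p)) / log(ncells)
}

#' Paired Difference Index for one species
#'
#' Species-level specialization from the gaps between the strongest link and
#' the rest. Flows are padded with zeros to the number of potential partners
#' `H`, sorted decreasingly and normalised so the largest is 1; then
#' `PDI = sum_{i=2..H} (1 - P_i) / (H - 1)`. 1 = perfect specialist, 0 =
#' uniform generalist.
#'
#' @param flows Nonnegative interaction frequencies of the species (its row
#'   or column of the web), max > 0.
#' @param n_potential_partners Number of potential partners `H >= 2`
#'   (default: `length(flows)`).
#' @return PDI in \[0, 1\].
#' @export
pdi <- function(flows, n_potential_partners = length(flows)) {
  h <- n_potential_partners
  if (h < 2) stop("PDI undefined for fewer than 2 potential partners",
                  call. = FALSE)
  if (length(flows) > h) stop("more flows than potential partners",
                              call. = FALSE)
  if (max(flows) <= 0) stop("species has no positive flow", call. = FALSE)
  p <- sort(c(flows, rep(0, h - length(flows))), decreasing = TRUE)
  p <- p / p[1]
  sum(p[1] - p[-1]) / (h - 1)
}

#' Network-level mean PDI
#'
#' Weighted mean of species-level PDI pooled over both guilds, each species
#' weighted by its total interaction frequency. A bird's potential partners
#' are the network's plants and vice versa; a guild whose partner guild has
#' fewer than 2 members is skipped with a warning.
#'
#' @param net A cleaned `interaction_matrix`.
#' @param guilds `"both"` (default), `"plants"` or `"birds"`.
#' @return Weighted mean PDI in \[0, 1\].
#' @export
mean_pdi <- function(net, guilds = c("both", "plants", "birds")) {
  guilds <- match.arg(guilds)
  w <- unclass(net)
  vals <- numeric(0)
  wts <- numeric(0)
  if (guilds %in% c("both", "plants")) {
    if (ncol(w) >= 2) {
      vals <- c(vals, apply(w, 1, pdi, n_potential_partners = ncol(w)))
      wts <- c(wts, rowSums(w))
    } else {
      warning("plants skipped: fewer than 2 potential bird partners",
              call. = FALSE)
    }
  }
  if (guilds %in% c("both", "birds")) {
    if (nrow(w) >= 2) {
      vals <- c(vals, apply(w, 2, pdi, n_potential_partners = nrow(w)))
      wts <- c(wts, colSums(w))
    } else {
      warning("birds skipped: fewer than 2 potential plant partners",
              call. = FALSE)
    }
  }
  if (length(vals) == 0L) stop("no species with a defined PDI",
                               call. = FALSE)
  sum(vals * wts) / sum(wts)
}

#' Five-metric structural profile of a network
#'
#' @param net A cleaned `interaction_matrix`.
#' @param seed Seed for the modularity search (deterministic given seed).
#' @param restarts Restarts for the modularity search.
#' @return One-row data frame: `network_id`, `weighted_connectance`,
#'   `wnodf`, `interaction_evenness`, `mean_pdi`, `modularity_q`.
#' @export
structural_profile <- function(net, seed = 1L, restarts = 10L) {
  part <- dirtlpawb_modularity(net, seed = seed, restarts = restarts)
  data.frame(network_id = network_id(net),
             weighted_connectance = weighted_connectance(net),
             wnodf = wnodf(net),
             interaction_evenness = interaction_evenness(net),
             mean_pdi = mean_pdi(net),
             modularity_q = part$q,
             stringsAsFactors = FALSE)
}

#' @rdname structural_profile
#' @param nets List of `interaction_matrix` objects.
#' @export
structural_profiles <- function(nets, seed = 1L, restarts = 10L) {
  do.call(rbind, lapply(nets, structural_profile, seed = seed,
                        restarts = restarts))
}

#' PCA-composite structural dissimilarity
#'
#' Z-scores the five structure metrics, runs a PCA, retains the leading
#' components reaching `variance_target` (or exactly `n_components`), and
#' returns the Euclidean distance between retained score vectors as a
#' network structural dissimilarity matrix.
#'
#' @param profiles Data frame from [structural_profiles()].
#' @param variance_target Variance fraction to reach (default 0.85).
#' @param n_components Exact component count override.
#' @return A `dist_matrix` over networks.
#' @export
structural_dissimilarity <- function(profiles, variance_target = 0.85,
                                     n_components = NULL) {
  if (nrow(profiles) < 3L) stop("need at least 3 profiles", call. = FALSE)
  x <- as.matrix(profiles[, setdiff(names(profiles), "network_id"),
                          drop = FALSE])
  rownames(x) <- profiles$network_id
  if (all(apply(x, 2, stats::sd) == 0)) {
    # identical profiles: no structural variation, all distances zero
    warning("all profiles identical; structural distances are all zero",
            call. = FALSE)
    return(dist_matrix(matrix(0, nrow(x), nrow(x)),
                       labels = rownames(x)))
  }
  pca_score_distance(x, variance_target, n_components)
}
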