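# Barber bipartite modularity and its weighted label-propagation optimiser.

#' Barber modularity of a module partition
#'
#' `Q = (1/F) * sum_ij (w_ij - r_i c_j / F) * 1[g(plant_i) == g(bird_j)]`
#' with `r_i`, `c_j` the marginal totals and `F` the grand total: the excess
#' of within-module weight over a degree-based null expectation.
#'
#' @param net An `interaction_matrix`.
#' @param partition A `module_partition` (see [module_partition()]) or a
#'   list with integer vectors `plants` and `birds` giving a module index
#'   for every species.
#' @return Modularity Q in \[-1, 1\].
#' @export
barber_modularity <- function(net, partition) {
  gp <- partition$plants
  gb <- partition$birds
  if (length(gp) != n_plants(net) || length(gb) != n_birds(net) ||
      anyNA(gp) || anyNA(gb)) {
    stop("partition must assign every plant and bird to a module",
         call. = FALSE)
  }
  w <- unclass(net)
  f <- sum(w)
  same <- outer(gp, gb, "==")
  sum((w - outer(rowSums(w), colSums(w)) / f) * same) / f
}

#' Construct a module partition
#'
#' @param plants,birds Integer module indices, named by species id.
#' @param q Modularity of the assignment (computed by the optimiser).
#' @return A `module_partition` object.
#' @export
module_partition <- function(plants, birds, q = NA_real_) {
  structure(list(plants = plants, birds = birds, q = q,
                 n_modules = length(unique(c(plants, birds)))),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition: %d modules, Q = %.4f>\n",
              x$n_modules, x$q))
  invisible(x)
}

#' Weighted modularity search by label propagation (DIRTLPAwb+ style)
#'
#' Maximises Barber's weighted bipartite modularity with the
#' label-propagation-plus-agglomeration heuristic: nodes are repeatedly
#' relabelled to the module giving the largest Q gain (a fresh module is
#' always a candidate), exhausted sweeps are followed by module-merge
#' sweeps, and the search restarts from `restarts` seeded random
#' initialisations at every candidate module count from 1 to the smaller
#' guild size; the best assignment wins. Ties break to the lowest module
#' index.
#'
#' @param net A cleaned `interaction_matrix`.
#' @param seed Integer seed; results are reproducible given the seed.
#' @param restarts Random initialisations per candidate module count
#'   (default 10).
#' @return A `module_partition` whose `q` equals
#'   [barber_modularity()] of the returned assignment.
#' @export
dirtlpawb_modularity <- function(net, seed = 1L, restarts = 10L) {
  w <- unclass(net)
  np <- nrow(w); nb <- ncol(w)
  if (np == 1L && nb == 1L) {
    return(module_partition(
      stats::setNames(1L, plant_ids(net)),
      stats::setNames(1L, bird_ids(net)), q = 0))
  }
  best <- NULL
  with_seed(seed, {
    # canonical label-propagation starts: every node of one guild in its
    # own module, the other guild adopting its best-matching label
    init_from_plants <- function(gp) {
      gb <- apply(w, 2, function(col) {
        s <- rowsum_by(col, gp)
        as.integer(names(s)[which.max(s)])
      })
      lpawb_with_kicks(w, gp, gb)
    }
    best <- init_from_plants(seq_len(np))
    gb0 <- seq_len(nb)
    gp0 <- apply(w, 1, function(row) {
      s <- rowsum_by(row, gb0)
      as.integer(names(s)[which.max(s)])
    })
    res <- lpawb_with_kicks(w, gp0, gb0)
    if (res$q > best$q + 1e-14) best <- res
    for (k0 in seq_len(min(np, nb))) {
      for (r in seq_len(restarts)) {
        gp <- sample.int(k0, np, replace = TRUE)
        gb <- apply(w, 2, function(col) {
          s <- rowsum_by(col, gp)
          as.integer(names(s)[which.max(s)])
        })
        res <- lpawb_with_kicks(w, gp, gb)
        if (is.null(best) || res$q > best$q + 1e-14) best <- res
      }
    }
  })
  part <- module_partition(
    stats::setNames(relabel_modules(best$gp, best$gb)$gp, plant_ids(net)),
    stats::setNames(relabel_modules(best$gp, best$gb)$gb, bird_ids(net)))
  part$q <- barber_modularity(net, part)
  part
}

# sum x by integer groups, names = group id
rowsum_by <- function(x, g) {
  out <- rowsum(x, g)
  stats::setNames(out[, 1], rownames(out))
}

# optimise, then try seeded basin-hopping kicks: perturb a few nodes and
# re-optimise, keeping improvements
lpawb_with_kicks <- function(w, gp, gb, kicks = 3L) {
  res <- lpawb_optimise(w, gp, gb)
  np <- nrow(w); nb <- ncol(w)
  for (k in seq_len(kicks)) {
    gp2 <- res$gp
    gb2 <- res$gb
    mods <- unique(c(gp2, gb2))
    pool <- c(mods, max(mods) + 1L)
    ip <- sample.int(np, max(1L, np %/% 3))
    ib <- sample.int(nb, max(1L, nb %/% 3))
    gp2[ip] <- sample(pool, length(ip), replace = TRUE)
    gb2[ib] <- sample(pool, length(ib), replace = TRUE)
    cand <- lpawb_optimise(w, gp2, gb2)
    if (cand$q > res$q + 1e-14) res <- cand
  }
  res
}

# hill-climb: node moves until stable, then module merges, iterated
lpawb_optimise <- function(w, gp, gb) {
  f <- sum(w)
  r <- rowSums(w); cc <- colSums(w)
  q <- barber_q_fast(w, gp, gb, f, r, cc)
  repeat {
    moved <- TRUE
    while (moved) {
      moved <- FALSE
      res <- sweep_side(w, gp, gb, r, cc, f, plants = TRUE)
      if (res$improved) { gp <- res$g; moved <- TRUE }
      res <- sweep_side(t(w), gb, gp, cc, r, f, plants = TRUE)
      if (res$improved) { gb <- res$g; moved <- TRUE }
    }
    merged <- merge_modules(w, gp, gb, r, cc, f)
    if (!merged$improved) break
    gp <- merged$gp; gb <- merged$gb
  }
  list(gp = gp, gb = gb, q = barber_q_fast(w, gp, gb, f, r, cc))
}

barber_q_fast <- function(w, gp, gb, f, r, cc) {
  sum((w - outer(r, cc) / f) * outer(gp, gb, "==")) / f
}

# one relabelling sweep over the rows of w (their groups in g_focal);
# g_other labels the columns. Node order is randomised per sweep so
# restarts explore different move sequences. Returns possibly-updated
# labels.
sweep_side <- function(w, g_focal, g_other, marg_focal, marg_other, f,
                       plants = TRUE) {
  improved <- FALSE
  mods <- sort(unique(c(g_focal, g_other)))
  free <- max(mods) + 1L                      # always-available fresh module
  cand <- c(mods, free)
  c_other <- vapply(cand, function(m) sum(marg_other[g_other == m]),
                    numeric(1))
  for (i in sample(seq_along(g_focal))) {
    s <- vapply(cand, function(m) sum(w[i, g_other == m]), numeric(1))
    score <- s / f - marg_focal[i] * c_other / f^2
    bestm <- cand[which.max(score)]           # which.max: lowest index ties
    cur <- match(g_focal[i], cand)
    if (score[match(bestm, cand)] > score[cur] + 1e-14) {
      g_focal[i] <- bestm
      improved <- TRUE
    }
  }
  list(g = g_focal, improved = improved)
}

# greedy agglomeration: accept the best positive-gain module merge, repeat
merge_modules <- function(w, gp, gb, r, cc, f) {
  improved_any <- FALSE
  repeat {
    mods <- sort(unique(c(gp, gb)))
    if (length(mods) < 2L) break
    rs <- vapply(mods, function(m) sum(r[gp == m]), numeric(1))
    cs <- vapply(mods, function(m) sum(cc[gb == m]), numeric(1))
    wmat <- matrix(0, length(mods), length(mods))
    for (a in seq_along(mods)) {
      ia <- gp == mods[a]
      if (!any(ia)) next
      for (b in seq_along(mods)) {
        jb <- gb == mods[b]
        if (any(jb)) wmat[a, b] <- sum(w[ia, jb])
      }
    }
    best_gain <- 0; best_ab <- NULL
    for (a in seq_len(length(mods) - 1)) {
      for (b in seq(a + 1, length(mods))) {
        # merging b into a: cross terms become within-module
        gain <- (wmat[a, b] + wmat[b, a]) / f -
          (rs[a] * cs[b] + rs[b] * cs[a]) / f^2
        if (gain > best_gain + 1e-14) {
          best_gain <- gain; best_ab <- c(a, b)
        }
      }
    }
    if (is.null(best_ab)) break
    gp[gp == mods[best_ab[2]]] <- mods[best_ab[1]]
    gb[gb == mods[best_ab[2]]] <- mods[best_ab[1]]
    improved_any <- TRUE
  }
  list(gp = gp, gb = gb, improved = improved_any)
}

# compact module ids to 1..k in order of first appearance
relabel_modules <- function(gp, gb) {
  all_g <- c(gp, gb)
  ids <- unique(all_g)
  map <- stats::setNames(seq_along(ids), ids)
  list(gp = unname(map[as.character(gp)]),
       gb = unname(map[as.character(gb)]))
}

# evaluate code with a temporary RNG seed, restoring global state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
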