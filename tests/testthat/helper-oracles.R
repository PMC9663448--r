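# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (explicit loops, set enumeration) so they cannot share
# a defect with the vectorised implementations they check.

# random labelled network without zero margins, dims 2..max_dim
random_net <- function(id, max_dim = 6, plant_pool = paste0("p", 1:8),
                       bird_pool = paste0("b", 1:8)) {
  repeat {
    np <- sample(2:max_dim, 1)
    nb <- sample(2:max_dim, 1)
    w <- matrix(stats::rpois(np * nb, 1.2) *
                  (stats::runif(np * nb) < 0.7), np, nb)
    if (any(w > 0) && all(rowSums(w) > 0) && all(colSums(w) > 0)) break
  }
  interaction_matrix(w, id,
                     plant_ids = sample(plant_pool, np),
                     bird_ids = sample(bird_pool, nb))
}

# Sorensen via explicit element loops
sorensen_oracle <- function(a, b) {
  a <- unique(a); b <- unique(b)
  sh <- 0
  for (x in a) if (any(b == x)) sh <- sh + 1
  ua <- length(a) - sh
  ub <- length(b) - sh
  (ua + ub) / (2 * sh + ua + ub)
}

links_of <- function(net) {
  out <- character(0)
  for (i in seq_len(nrow(net))) {
    for (j in seq_len(ncol(net))) {
      if (net[i, j] > 0) {
        out <- c(out, paste(rownames(net)[i], colnames(net)[j], sep = "&"))
      }
    }
  }
  out
}

beta_s_oracle <- function(na, nb) {
  sa <- c(paste0("pl.", rownames(na)), paste0("bi.", colnames(na)))
  sb <- c(paste0("pl.", rownames(nb)), paste0("bi.", colnames(nb)))
  sorensen_oracle(sa, sb)
}

beta_wn_oracle <- function(na, nb) sorensen_oracle(links_of(na),
                                                   links_of(nb))

beta_os_oracle <- function(na, nb) {
  sp <- intersect(rownames(na), rownames(nb))
  sb <- intersect(colnames(na), colnames(nb))
  if (length(sp) == 0 || length(sb) == 0) return(NA_real_)
  la <- links_of(interaction_ok(unclass(na)[sp, sb, drop = FALSE]))
  lb <- links_of(interaction_ok(unclass(nb)[sp, sb, drop = FALSE]))
  if (length(la) == 0 && length(lb) == 0) return(NA_real_)
  sorensen_oracle(la, lb)
}

# subweb may be all-zero; keep it as a plain labelled matrix
interaction_ok <- function(m) m

# literal per-cell transcription of the weighted NODF rules, applied to the
# matrix pre-sorted by decreasing marginal totals (the "decreasing fill"
# presentation)
wnodf_oracle <- function(m) {
  m <- m[order(rowSums(m), decreasing = TRUE),
         order(colSums(m), decreasing = TRUE), drop = FALSE]
  contribs <- numeric(0)
  half <- function(mm) {
    res <- numeric(0)
    n <- nrow(mm)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        mt_i <- sum(mm[i, ]); mt_j <- sum(mm[j, ])
        f_i <- sum(mm[i, ] > 0); f_j <- sum(mm[j, ] > 0)
        if (!(mt_i > mt_j) || f_i < f_j || f_j == 0) {
          res <- c(res, 0)
        } else {
          k <- 0
          for (col in seq_len(ncol(mm))) {
            if (mm[j, col] > 0 && mm[j, col] < mm[i, col]) k <- k + 1
          }
          res <- c(res, 100 * k / f_j)
        }
      }
    }
    res
  }
  contribs <- c(half(m), half(t(m)))
  sum(contribs) / (choose(nrow(m), 2) + choose(ncol(m), 2))
}

# Barber Q by direct double loop
barber_q_oracle <- function(w, gp, gb) {
  f <- sum(w)
  r <- rowSums(w); cc <- colSums(w)
  q <- 0
  for (i in seq_len(nrow(w))) {
    for (j in seq_len(ncol(w))) {
      if (gp[i] == gb[j]) q <- q + (w[i, j] - r[i] * cc[j] / f) / f
    }
  }
  unname(q)
}

# all set partitions of n elements as assignment vectors (restricted growth)
set_partitions <- function(n) {
  parts <- list()
  rec <- function(prefix, maxg) {
    i <- length(prefix) + 1L
    if (i > n) {
      parts[[length(parts) + 1L]] <<- prefix
      return(invisible())
    }
    for (g in seq_len(maxg + 1L)) rec(c(prefix, g), max(maxg, g))
  }
  rec(integer(0), 0L)
  parts
}

# exact modularity maximum: enumerate plant partitions; given one, each
# bird independently joins its best module (or none, contributing 0)
exhaustive_max_q <- function(w) {
  f <- sum(w)
  r <- rowSums(w); cc <- colSums(w)
  best <- -Inf
  for (gp in set_partitions(nrow(w))) {
    mods <- unique(gp)
    q <- 0
    for (j in seq_len(ncol(w))) {
      contrib <- vapply(mods, function(m) {
        sum(w[gp == m, j]) / f - sum(r[gp == m]) * cc[j] / f^2
      }, numeric(1))
      q <- q + max(0, max(contrib))
    }
    if (q > best) best <- q
  }
  best
}

# bare weight matrix of a network (drops the class and id attribute)
weights_of <- function(net) {
  m <- unclass(net)
  attr(m, "network_id") <- NULL
  m
}

# tiny deterministic 3x3 fixture used across files
toy_net <- function(id = "toy") {
  interaction_matrix(
    matrix(c(4, 1, 0,
             2, 0, 1,
             0, 3, 2), 3, 3, byrow = TRUE,
           dimnames = list(c("p1", "p2", "p3"), c("b1", "b2", "b3"))),
    id)
}

# minimal valid metadata table for a set of network ids
toy_metadata <- function(ids, eco = NULL, biome = NULL) {
  n <- length(ids)
  if (is.null(eco)) eco <- rep_len(c("E1", "E2"), n)
  if (is.null(biome)) biome <- sub("_.*", "", sub("E", "B", eco))
  data.frame(network_id = ids, study_id = rep_len(c("s1", "s2"), n),
             latitude = seq(-10, 10, length.out = n),
             longitude = seq(0, 20, length.out = n),
             elevation = seq(100, 1000, length.out = n),
             ecoregion_id = eco, biome_id = biome,
             human_footprint = seq(1, 30, length.out = n),
             sampling_hours = rep_len(c(50, 120), n),
             sampling_months = rep_len(c(3, 8), n),
             sampling_year_mean = rep_len(c(2000, 2010), n),
             sampling_intensity = rep_len(c(0.4, 0.8), n),
             method_design = rep_len(c("transect", "plot"), n),
             method_focus = rep_len(c("phytocentric", "zoocentric"), n),
             method_frequency_type = rep_len(c("visits", "fruits_eaten"), n),
             method_coverage = rep_len(c("total", "partial"), n),
             stringsAsFactors = FALSE)
}
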