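test_that("dist_matrix enforces symmetry, zero diagonal and binary
           content", {
  m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  expect_s3_class(dist_matrix(m, kind = "binary"), "dist_matrix")
  bad <- m; bad[1, 2] <- 2; bad[2, 1] <- 2
  expect_error(dist_matrix(bad, kind = "binary"), "0/1")
  expect_error(dist_matrix(bad * NA), "non-finite")
  asym <- m; asym[1, 2] <- 0.5
  expect_error(dist_matrix(asym), "symmetric")
  dd <- m; diag(dd) <- 1
  expect_error(dist_matrix(dd), "diagonal")
  # CSV round trip
  d <- dist_matrix(matrix(c(0, 2, 2, 0), 2),
                   labels = c("x", "y"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_dist_matrix(d, f)
  expect_equal(unclass(read_dist_matrix(f)), unclass(d))
})

test_that("binary membership distance encodes same/distinct regions and
           respects nesting", {
  d <- binary_membership_distance(c(n1 = "E1", n2 = "E1", n3 = "E2"))
  expect_equal(unclass(d)["n1", "n2"], 0)
  expect_equal(unclass(d)["n1", "n3"], 1)
  expect_equal(unclass(d)["n2", "n3"], 1)
  expect_equal(max(unclass(binary_membership_distance(
    c(a = "E", b = "E", c = "E")))), 0)
  expect_error(binary_membership_distance(c(a = "E", b = NA)), "missing")
  # nesting: same ecoregion implies same biome distance 0
  md <- toy_metadata(sprintf("n%d", 1:6),
                     eco = c("E1_1", "E1_1", "E1_2", "E2_1", "E2_1",
                             "E2_2"),
                     biome = c("B1", "B1", "B1", "B2", "B2", "B2"))
  de <- binary_membership_distance(setNames(md$ecoregion_id,
                                            md$network_id))
  db <- binary_membership_distance(setNames(md$biome_id, md$network_id))
  expect_true(all(unclass(db)[unclass(de) == 0] == 0))
})

test_that("environmental PCA distance reduces to scaled Euclidean when all
           components are retained", {
  set.seed(5)
  env <- data.frame(region_id = paste0("R", 1:6),
                    temp = rnorm(6, 15, 5), temp_seas = rnorm(6, 40, 10),
                    rain = rnorm(6, 1200, 300), rain_seas = rnorm(6, 30, 8),
                    slope = runif(6, 0, 20), footprint = runif(6, 0, 30))
  d <- environmental_distance(env, n_components = 6)
  z <- scale(as.matrix(env[, -1]))
  expect_equal(max(abs(unclass(d) - as.matrix(dist(z)))), 0,
               tolerance = 1e-8)
  # identical rows at distance zero
  env2 <- env
  env2[2, -1] <- env2[1, -1]
  d2 <- environmental_distance(env2)
  expect_equal(unclass(d2)["R1", "R2"], 0, tolerance = 1e-10)
  # single informative variable: distance proportional to scaled diff
  env3 <- data.frame(region_id = c("A", "B", "C"), x = c(0, 1, 3),
                     y = c(2, 2, 2))
  expect_warning(d3 <- environmental_distance(env3, n_components = 1),
                 "constant")
  v <- unclass(d3)
  expect_equal(v["A", "C"] / v["A", "B"], 3, tolerance = 1e-8)
})

test_that("region-to-network expansion is a pure lookup preserving the
           matrix invariants", {
  env <- data.frame(region_id = c("E1", "E2"), x = c(0, 3), y = c(1, 5))
  rd <- environmental_distance(env, n_components = 2)
  memb <- c(n1 = "E1", n2 = "E1", n3 = "E2")
  d <- expand_to_networks(rd, memb)
  expect_equal(unclass(d)["n1", "n2"], 0)
  expect_equal(unclass(d)["n1", "n3"], unclass(rd)["E1", "E2"])
  expect_equal(unclass(d)["n2", "n3"], unclass(rd)["E1", "E2"])
  expect_error(expand_to_networks(rd, c(n1 = "E9")), "absent")
  # same-region zeros mirror the binary matrix's zeros
  db <- binary_membership_distance(memb)
  expect_true(all(unclass(d)[unclass(db) == 0] == 0))
})

test_that("absolute difference distance is the 1-D Euclidean metric", {
  d <- absolute_difference_distance(c(a = 3, b = 7, c = 7))
  expect_equal(unclass(d)["a", "b"], 4)
  expect_equal(unclass(d)["b", "c"], 0)
  expect_warning(d2 <- absolute_difference_distance(c(a = 1, b = NA,
                                                      c = 2)),
                 "missing")
  expect_equal(dm_labels(d2), c("a", "c"))
})

test_that("Haversine distances hit analytic great-circle values and the
           triangle inequality", {
  co <- data.frame(network_id = c("o", "anti", "pole", "same"),
                   latitude = c(0, 0, 90, 0), longitude = c(0, 180, 0, 0))
  d <- unclass(haversine_distance(co))
  r <- 6371.0088
  expect_equal(d["o", "anti"], pi * r, tolerance = 1e-9)
  expect_equal(d["o", "pole"], pi * r / 2, tolerance = 1e-9)
  expect_equal(d["o", "same"], 0)
  expect_error(haversine_distance(data.frame(network_id = "x",
                                             latitude = 91,
                                             longitude = 0)), "invalid")
  set.seed(15)
  pts <- data.frame(network_id = paste0("s", 1:12),
                    latitude = runif(12, -90, 90),
                    longitude = runif(12, -180, 180))
  m <- unclass(haversine_distance(pts))
  for (i in 1:12) for (j in 1:12) for (k in 1:12) {
    expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-6)
  }
})

test_that("Gower mixed distance matches cluster::daisy and stays in
           [0, 1]", {
  tab <- data.frame(network_id = paste0("n", 1:5),
                    design = c("a", "a", "b", "c", "b"),
                    effort = c(0, 5, 10, 2.5, 10),
                    cover = c("t", "p", "t", "p", "t"),
                    stringsAsFactors = FALSE)
  g <- gower_mixed_distance(tab)
  expect_true(all(unclass(g) >= 0 & unclass(g) <= 1))
  skip_if_not_installed("cluster")
  ref <- as.matrix(cluster::daisy(
    data.frame(design = factor(tab$design), effort = tab$effort,
               cover = factor(tab$cover)), metric = "gower"))
  expect_equal(max(abs(unclass(g) - ref)), 0, tolerance = 1e-10)
  # hand case: one categorical match + one quantitative at half range
  t2 <- data.frame(network_id = c("x", "y"), cat = c("u", "u"),
                   q = c(0, 5))
  t2$q <- c(0, 5)
  g2 <- gower_mixed_distance(rbind(t2, data.frame(network_id = "z",
                                                  cat = "u", q = 10)))
  expect_equal(unclass(g2)["x", "y"], 0.25)
  # all-categorical full mismatch -> 1
  t3 <- data.frame(network_id = c("x", "y"), a = c("1", "2"),
                   b = c("u", "v"))
  expect_equal(unclass(gower_mixed_distance(t3))["x", "y"], 1)
})

test_that("principal coordinates reproduce Euclidean configurations", {
  set.seed(25)
  pts <- matrix(rnorm(30), 15, 2)
  D <- dist_matrix(as.matrix(dist(pts)), labels = paste0("u", 1:15))
  co <- pcoa(D, 2)
  expect_equal(max(abs(as.matrix(dist(co)) - unclass(D))), 0,
               tolerance = 1e-8)
  # agreement with the classical-scaling reference implementation
  skip_if_not_installed("ape")
  ref <- ape::pcoa(as.dist(unclass(D)))
  expect_equal(abs(co), abs(ref$vectors[, 1:2]), tolerance = 1e-6,
               ignore_attr = TRUE)
  # two points: one axis at +/- d/2
  D2 <- dist_matrix(matrix(c(0, 4, 4, 0), 2), labels = c("a", "b"))
  co2 <- pcoa(D2, 1)
  expect_equal(sort(co2[, 1]), c(-2, 2), ignore_attr = TRUE)
  # zero matrix: coordinates all zero
  D0 <- dist_matrix(matrix(0, 3, 3), labels = c("a", "b", "c"))
  expect_equal(max(abs(pcoa(D0, 2))), 0)
  # axis overflow names the positive-eigenvalue count
  expect_error(pcoa(D2, 2), "positive eigenvalues")
})

test_that("methods distance collapses identical protocols and is column-
           order invariant", {
  md <- toy_metadata(paste0("n", 1:6))
  cols <- c("network_id", "method_design", "method_focus",
            "method_frequency_type", "method_coverage")
  d <- methods_distance(md[, cols])
  expect_s3_class(d, "dist_matrix")
  # identical method rows are at distance zero (rows alternate two
  # protocols in the fixture)
  expect_equal(unclass(d)["n1", "n3"], 0, tolerance = 1e-10)
  expect_equal(unclass(d)["n2", "n4"], 0, tolerance = 1e-10)
  # two protocols -> a single positive cross value
  off <- unclass(d)["n1", "n2"]
  expect_gt(off, 0)
  expect_equal(unclass(d)["n3", "n6"], off, tolerance = 1e-10)
  d2 <- methods_distance(md[, cols[c(1, 5, 3, 2, 4)]])
  expect_equal(unclass(d), unclass(d2), tolerance = 1e-10)
})

test_that("lower-triangle vectorization is a bijection in a fixed pair
           order", {
  set.seed(35)
  m <- matrix(runif(25), 5, 5)
  m <- m + t(m)
  diag(m) <- 0
  d <- dist_matrix(m, labels = c("c", "a", "e", "b", "d"))
  v <- vectorize_lower_triangle(d)
  expect_equal(length(v$values), 10)
  expect_identical(v$pairs$id_a[1], "a")
  # values match the matrix entries pair by pair
  for (r in seq_len(nrow(v$pairs))) {
    expect_equal(v$values[r],
                 unclass(d)[v$pairs$id_a[r], v$pairs$id_b[r]])
  }
  back <- devectorize(v$values, v$pairs)
  expect_equal(unclass(back)[dm_labels(d), dm_labels(d)], unclass(d),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(vectorize_lower_triangle(d, label_order = c("a", "b")),
               "label_order")
})
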