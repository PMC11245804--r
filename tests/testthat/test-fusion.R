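# Fusion of per-source embeddings: concatenation identities, normalised
# cluster distances and softmax probability blocks.

test_that("concatenation lengths add up across sources", {
  n <- 4
  parts3 <- list(diagnosis = matrix(0, n, 1000), tags = matrix(0, n, 32),
                 image = matrix(0, n, 500))
  f3 <- fuse_embeddings(parts3)
  expect_equal(ncol(f3), 1532)
  expect_equal(ncol(fuse_embeddings(parts3[c("diagnosis", "tags")])), 1032)
  expect_equal(ncol(fuse_embeddings(parts3[c("diagnosis", "image")])), 1500)
  expect_equal(ncol(fuse_embeddings(parts3[c("tags", "image")])), 532)
  spans <- attr(f3, "component_spans")
  expect_equal(unname(spans$image), c(1033, 1532))
  # single part is the identity
  one <- matrix(rnorm(8), 4, 2)
  expect_equal(unclass(fuse_embeddings(list(a = one)))[, ], one,
               ignore_attr = TRUE)
  # purity: identical parts give identical fused vectors
  p <- list(a = matrix(1:8, 4), b = matrix(8:1, 4))
  expect_identical(fuse_embeddings(p)[2, ], fuse_embeddings(p)[2, ])
  expect_error(fuse_embeddings(list(a = matrix(0, 3, 2), b = matrix(0, 4, 2))),
               "equal row counts")
})

fitted_sources <- function(kappas, n = 200, d = 6, seed = 4) {
  set.seed(seed)
  parts <- lapply(kappas, function(k) matrix(rnorm(n * d), n, d))
  names(parts) <- names(kappas)
  models <- lapply(seq_along(kappas), function(i)
    fit_cluster(parts[[i]], "kmeans", "euclidean", kappas[[i]], seed = i))
  names(models) <- names(kappas)
  list(parts = parts, models = models)
}

test_that("cluster-distance fusion has length sum(kappa) and lies in [0,1]", {
  s <- fitted_sources(c(diagnosis = 20L, tags = 25L, image = 40L))
  f <- fuse_clusterdists(s$parts, s$models)
  expect_equal(ncol(f), 85)
  expect_true(all(f >= 0 & f <= 1))
  s2 <- fitted_sources(c(tags = 25L, image = 40L))
  expect_equal(ncol(fuse_clusterdists(s2$parts, s2$models)), 65)
  s3 <- fitted_sources(c(diagnosis = 20L, tags = 25L))
  expect_equal(ncol(fuse_clusterdists(s3$parts, s3$models)), 45)
  s4 <- fitted_sources(c(diagnosis = 20L, image = 40L))
  expect_equal(ncol(fuse_clusterdists(s4$parts, s4$models)), 60)

  # a record sitting on a centre attains its block minimum there
  m <- s$models$tags
  parts_at_centre <- s$parts
  parts_at_centre$tags[1, ] <- m$centres[3, ]
  fc <- fuse_clusterdists(parts_at_centre, s$models)
  block <- fc[1, 21:45]
  expect_equal(which.min(block), 3L)
  expect_error(fuse_clusterdists(s$parts, list(1, 2, 3)), "unfitted")
})

test_that("normalisers fitted on training data are reapplied with clipping", {
  s <- fitted_sources(c(tags = 5L))
  tr <- fuse_clusterdists(lapply(s$parts, function(p) p[1:100, ]), s$models)
  norms <- attr(tr, "normalisers")
  far <- lapply(s$parts, function(p) p * 100)   # far outside training range
  fc <- fuse_clusterdists(far, s$models, normalisers = norms)
  expect_true(all(fc >= 0 & fc <= 1))
  expect_equal(max(fc), 1)  # clipped at the training maximum
})

test_that("probability fusion follows the softmax of negated distances", {
  s <- fitted_sources(c(diagnosis = 4L, tags = 3L))
  f <- fuse_clusterprobs(s$parts, s$models)
  expect_equal(ncol(f), 7)
  spans <- attr(f, "component_spans")
  for (sp in spans) {
    block <- f[, sp["start"]:sp["end"], drop = FALSE]
    expect_true(all(abs(rowSums(block) - 1) < 1e-9))
    expect_true(all(block > 0 & block < 1))
  }
  # closed form: distances (0, ln 2) give probabilities (2/3, 1/3)
  x <- matrix(c(0, 0), 1, 2)
  m <- structure(list(algorithm = "kmeans", metric = "euclidean", k = 2L,
                      centres = rbind(c(0, 0), c(log(2), 0)),
                      medoid_idx = NULL, cluster = NULL, inertia = 0,
                      seed = 1L, empty_cluster = FALSE),
                 class = "radclust_cluster")
  p <- fuse_clusterprobs(list(src = x), list(m), use_normalised = FALSE)
  expect_equal(as.vector(p), c(2 / 3, 1 / 3), tolerance = 1e-12)
  # equal distances share probability equally; shorter distance wins
  m4 <- structure(list(algorithm = "kmeans", metric = "euclidean", k = 4L,
                       centres = rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)),
                       medoid_idx = NULL, cluster = NULL, inertia = 0,
                       seed = 1L, empty_cluster = FALSE),
                  class = "radclust_cluster")
  p4 <- fuse_clusterprobs(list(src = matrix(0, 1, 2)), list(m4),
                          use_normalised = FALSE)
  expect_equal(as.vector(p4), rep(0.25, 4))
  xq <- matrix(c(0.4, 0.1), 1, 2)
  pq <- fuse_clusterprobs(list(src = xq), list(m4), use_normalised = FALSE)
  d <- as.vector(radclust:::distance_matrix(xq, m4$centres, "euclidean"))
  expect_identical(order(as.vector(pq), decreasing = TRUE), order(d))
})
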