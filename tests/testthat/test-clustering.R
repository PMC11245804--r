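# k-means / k-medoids fits, kappa sweeps, Kneedle elbow and run stability.

test_that("well-separated blobs are recovered and oracles agree", {
  blobs <- make_blobs(25, rbind(c(0, 0), c(6, 6)), seed = 2)
  for (alg in c("kmeans", "kmedoids")) {
    m <- fit_cluster(blobs$x, alg, "euclidean", 2, seed = 1)
    expect_equal(nmi(blobs$y, m$cluster), 1)
    a <- predict(m, blobs$x)
    expect_identical(a$cluster, oracle_assign(blobs$x, m$centres, "euclidean"))
  }
  # cosine metric, including the exhaustive nearest-centre oracle
  set.seed(3)
  x <- matrix(rnorm(50 * 4), 50, 4) + 2
  m <- fit_cluster(x, "kmedoids", "cosine", 4, seed = 2)
  expect_identical(predict(m, x)$cluster, oracle_assign(x, m$centres, "cosine"))
  # medoids are data members
  expect_true(all(m$medoid_idx %in% seq_len(nrow(x))))
  expect_equal(m$centres, x[m$medoid_idx, ], ignore_attr = TRUE)
})

test_that("degenerate and invalid fits behave as specified", {
  set.seed(4)
  x <- matrix(rnorm(20), 10, 2)
  m <- fit_cluster(x, "kmedoids", "euclidean", 10, seed = 1)
  expect_equal(m$inertia, 0)                      # k = n
  expect_error(fit_cluster(x, "kmeans", "cosine", 2), "Euclidean")
  expect_error(fit_cluster(x, "kmeans", "euclidean", 1), "k must lie")
  # determinism given seed
  m1 <- fit_cluster(x, "kmeans", "euclidean", 3, seed = 9)
  m2 <- fit_cluster(x, "kmeans", "euclidean", 3, seed = 9)
  expect_identical(m1$centres, m2$centres)
})

test_that("assignment is invariant to consistent coordinate permutation", {
  set.seed(5)
  x <- matrix(rnorm(60 * 5), 60, 5)
  m <- fit_cluster(x, "kmeans", "euclidean", 4, seed = 3)
  perm <- sample(5)
  mp <- m; mp$centres <- m$centres[, perm]
  expect_identical(predict(m, x)$cluster, predict(mp, x[, perm])$cluster)
  # ties break toward the lowest cluster index
  mt <- m
  mt$centres <- rbind(c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0), c(9, 9, 9, 9, 9))
  expect_equal(predict(mt, matrix(c(1, 0, 0, 0, 0), 1))$cluster, 1L)
})

test_that("kappa sweeps cover the grid with non-increasing inertia", {
  blobs <- make_blobs(20, diag(5) * 8, seed = 6)
  grid <- c(2L, 3L, 5L, 8L, 12L, 20L, 40L)
  models <- sweep_kappa(blobs$x, "kmeans", "euclidean", kappa_grid = grid,
                        seed = 2)
  expect_length(models, 7)
  expect_named(models, as.character(grid))
  inert <- vapply(models, `[[`, 0, "inertia")
  expect_lte(inert[["40"]], inert[["2"]])
  single <- sweep_kappa(blobs$x, "kmeans", "euclidean", kappa_grid = 3L,
                        seed = 2)
  expect_length(single, 1)
  # the published grid has 11 values
  expect_length(eval(formals(sweep_kappa)$kappa_grid), 11)
})

test_that("the Kneedle elbow matches a chord-distance oracle", {
  grid <- c(5, 10, 15, 20, 25, 30, 40, 50, 75, 100, 150)
  y <- 1 / grid
  el <- find_elbow(grid, y)
  # oracle: maximum distance from the chord through the normalised endpoints
  xn <- (grid - min(grid)) / diff(range(grid))
  yn <- (y - min(y)) / diff(range(y))
  chord <- yn[1] + (yn[length(yn)] - yn[1]) * xn
  dist_to_chord <- chord - yn
  # the selected point attains the oracle maximum (ties allowed)
  expect_lt(max(dist_to_chord) - dist_to_chord[el$index], 1e-9)
  expect_false(el$flagged)

  # piecewise curve flat after 30 has its knee at 30
  y2 <- c(100, 80, 60, 40, 20, 10, 10, 10, 10, 10, 10)
  expect_equal(find_elbow(grid, y2)$kappa, 30)
  # strictly linear decrease has no knee: fallback is flagged
  lin <- find_elbow(seq(10, 100, 10), seq(100, 10, -10))
  expect_true(lin$flagged)
  expect_error(find_elbow(c(5, 10), c(2, 1)), "at least 3")
})

test_that("repeated runs are stable on well-separated data", {
  blobs <- make_blobs(30, rbind(c(0, 0), c(7, 0), c(0, 7)), seed = 8)
  sr <- stability_check(blobs$x, "kmeans", "euclidean", k = 3,
                         labels = list(class = blobs$y), runs = 11, seed = 5)
  expect_equal(nrow(sr$runs), 11)
  expect_lt(sr$summary$sd[sr$summary$metric == "nmi_class"], 0.05)
  sr2 <- stability_check(blobs$x, "kmeans", "euclidean", k = 3,
                          labels = list(class = blobs$y), runs = 11, seed = 5)
  expect_identical(sr, sr2)  # deterministic seed list
})
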