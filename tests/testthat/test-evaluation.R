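# Metric identities against independent oracles, composite scores,
# dissimilarity reports and cluster post-filters.

test_that("NMI and HS match hand computation on the worked example", {
  y <- c("A", "A", "B", "B"); yhat <- c(0, 0, 0, 1)
  # by hand: H(y) = ln 2; H(y|yhat) = 3/4 * H(2/3, 1/3)
  h23 <- -(2 / 3 * log(2 / 3) + 1 / 3 * log(1 / 3))
  expect_equal(hs(y, yhat), 1 - (0.75 * h23) / log(2), tolerance = 1e-12)
  expect_equal(round(hs(y, yhat), 4), 0.3113)
  i <- log(2) - 0.75 * h23
  hc <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(nmi(y, yhat), 2 * i / (log(2) + hc), tolerance = 1e-12)

  # perfect clustering up to relabelling, and the single-cluster floor
  expect_equal(nmi(y, c(7, 7, 3, 3)), 1)
  expect_equal(hs(y, c(7, 7, 3, 3)), 1)
  expect_equal(nmi(y, rep(1, 4)), 0)
  expect_equal(hs(y, rep(1, 4)), 0)
  expect_error(hs(rep("A", 4), yhat), "constant")
  expect_warning(v <- nmi(rep("A", 3), rep(1, 3)), "constant")
  expect_equal(v, 0)
})

test_that("metrics agree with the contingency oracle on random tables", {
  set.seed(10)
  for (trial in 1:100) {
    n <- sample(20:60, 1)
    y <- sample(letters[1:sample(2:5, 1)], n, replace = TRUE)
    yhat <- sample(seq_len(sample(2:6, 1)), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    o <- oracle_nmi_hs(y, yhat)
    expect_lt(abs(nmi(y, yhat) - o$nmi), 1e-10)
    expect_lt(abs(hs(y, yhat) - o$hs), 1e-10)
  }
  # invariance to relabelling and logarithm base (base cancels in ratios)
  y <- sample(c("M", "N", "O"), 40, replace = TRUE)
  yhat <- sample(1:4, 40, replace = TRUE)
  relab <- c(9, 2, 7, 5)[yhat]
  expect_equal(nmi(y, yhat), nmi(y, relab))
  expect_equal(hs(y, yhat), hs(y, relab))
})

test_that("the S score is the zero-aware harmonic mean of four metrics", {
  expect_equal(score_s(0.7, 0.7, 0.7, 0.7), 0.7)
  expect_equal(score_s(0, 0.5, 0.9, 1), 0)
  expect_equal(score_s(0.5, 0.5, 1, 1), 2 / 3)
  # the harmonic mean is bounded by the extremes and never exceeds the
  # arithmetic mean
  m <- c(0.43, 0.74, 0.52, 0.61)
  s <- score_s(m[1], m[2], m[3], m[4])
  expect_gte(s, min(m)); expect_lte(s, max(m)); expect_lte(s, mean(m))
})

test_that("cosine distance spans [0, 2] with the expected anchors", {
  expect_equal(cosine_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 1), c(-1, -1)), 2)
  expect_error(cosine_distance(c(0, 0), c(1, 1)), "zero")
})

test_that("within-cluster dissimilarity equals the exhaustive pair mean", {
  set.seed(11)
  emb <- matrix(rnorm(12 * 5), 12, 5)
  cl <- c(rep(1, 3), rep(2, 4), rep(3, 4), 4)
  dr <- cluster_dissimilarity(emb, cl)
  # brute-force oracle over every pair of every cluster
  brute <- vapply(1:3, function(c) {
    idx <- which(cl == c)
    pairs <- combn(idx, 2)
    mean(vapply(seq_len(ncol(pairs)), function(j)
      cosine_distance(emb[pairs[1, j], ], emb[pairs[2, j], ]), 0))
  }, 0)
  got <- dr$per_cluster$mean[dr$per_cluster$cluster %in% 1:3]
  expect_equal(got, brute, tolerance = 1e-12)
  expect_equal(dr$per_cluster$n_pairs[dr$per_cluster$cluster == 2], 6)
  expect_equal(dr$D, mean(brute))
  expect_equal(dr$excluded, 4)             # singleton excluded, reported
  # identical embeddings give zero dissimilarity
  same <- matrix(rep(c(1, 2, 3), each = 5), 5, 3, byrow = FALSE)
  expect_equal(cluster_dissimilarity(same, rep(1, 5))$D, 0, tolerance = 1e-12)
  # sampled mode flags the capped cluster and lands near the exact value
  big <- matrix(rnorm(300 * 4), 300, 4)
  exact <- cluster_dissimilarity(big, rep(1, 300))
  samp <- cluster_dissimilarity(big, rep(1, 300), max_pairs = 5000, seed = 2)
  expect_true(samp$per_cluster$sampled[1])
  expect_equal(samp$D, exact$D, tolerance = 0.05)
  expect_error(cluster_dissimilarity(emb[1:3, ], c(1, 2, 3)), "singleton")
})

test_that("D_score is the symmetric zero-aware harmonic mean", {
  expect_equal(d_score(0.03, 0.03), 0.03)
  expect_equal(d_score(0.02, 0.04), 4 / 150)
  expect_equal(d_score(0.02, 0.04), d_score(0.04, 0.02))
  expect_equal(d_score(0, 0.04), 0)
})

test_that("model selection ranks by S for images/diagnoses and by D for tags", {
  blobs <- make_blobs(30, rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0)), seed = 12)
  noise <- matrix(rnorm(90 * 3), 90, 3)
  grid <- c(2L, 3L, 5L, 8L, 15L)
  sw <- function(x) list(models = sweep_kappa(x, "kmeans", "euclidean",
                                              kappa_grid = grid, seed = 3),
                         embeddings = x)
  sweeps <- list(images = list(good = sw(blobs$x), bad = sw(noise)),
                 diagnoses = list(good = sw(blobs$x)),
                 tags = list(tight = sw(blobs$x), loose = sw(noise)))
  labels <- list(modality = blobs$y, body_part = c("p", "q", "r")[blobs$y])
  sel <- select_models(sweeps, labels)
  expect_equal(sel$winners$images, "good")   # separable beats noise on S
  expect_equal(sel$winners$diagnoses, "good")
  rr <- sel$report
  tag_rows <- rr[rr$source == "tags", ]
  expect_equal(sel$winners$tags,
               tag_rows$extractor[which.min(tag_rows$d_score)])
  expect_error(select_models(list(images = list()), labels), "must cover")
})

test_that("post-filters drop small and heterogeneous clusters", {
  set.seed(13)
  n_per <- 200
  labels <- list(
    modality = c(rep("M1", n_per), rep("M2", n_per),
                 sample(paste0("M", 1:10), 150, replace = TRUE),
                 rep("M3", 50)),
    body_part = c(rep("B1", n_per), rep("B2", n_per),
                  sample(paste0("B", 1:10), 150, replace = TRUE),
                  rep("B3", 50)))
  cl <- c(rep(1, n_per), rep(2, n_per), rep(3, 150), rep(4, 50))
  out <- filter_clusters(cl, labels, min_size = 100, entropy_cutoff = 0.9)
  log <- out$removal_log
  expect_false(log$removed[log$cluster == 1])   # pure cluster of 200 kept
  expect_true(log$removed[log$cluster == 3])    # uniform 10-way mixture
  expect_equal(log$reason[log$cluster == 3], "entropy")
  expect_gte(log$entropy_bodypart[log$cluster == 3], 0.9)
  expect_true(log$removed[log$cluster == 4])    # under the size floor
  expect_equal(log$reason[log$cluster == 4], "size")
  # survivors are re-indexed densely; removed records are NA
  expect_identical(sort(unique(out$cluster[!is.na(out$cluster)])), 1:2)
  expect_true(all(is.na(out$cluster[cl %in% c(3, 4)])))
})

test_that("the oversampling plan matches every cluster to the largest", {
  plan <- oversample_plan(c(rep(1, 10), rep(2, 4)))
  expect_equal(plan$replicas, c(0, 6))
  expect_equal(oversample_plan(rep(1, 7))$replicas, 0)
  plan2 <- oversample_plan(c(rep(1, 5), rep(2, 9), rep(3, 2), NA))
  expect_equal(sum(plan2$size + plan2$replicas), 3 * 9)
})
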