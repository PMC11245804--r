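# Shared fixtures, built once per run and cached.

.fix_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fix_cache)) {
    assign(name, force(expr), envir = .fix_cache)
  }
  get(name, envir = .fix_cache)
}

planted_groups <- function() {
  list(c("CR", "HEAD"), c("CT", "CHEST"), c("MR", "ABDOMEN"),
       c("XA", "FOOT"), c("RF", "SPINE"))
}

# small multi-purpose dataset: ~150 records, 5 planted groups
small_dataset <- function() {
  cached("small_ds", generate_dataset(fixture_config(
    n_exams = 50, seed = 42, groups = planted_groups(),
    files_per_exam_range = c(1, 5), image_side_range = c(32, 48))))
}

# reduced pipeline configuration used by the end-to-end tests
small_pipeline_config <- function(...) {
  radclust_config(
    tag_ae = tag_ae_config(layer_sizes = c(64L, 48L, 32L), bottleneck = 8L,
                           max_epochs = 25L),
    cae = cae_config(encoder_filters = c(4L, 8L), final_filters = 8L,
                     learning_rate = 1e-3, max_epochs = 2L,
                     batch_size = 16L, train_sample = 64L),
    image_pca_components = 32L,
    doc2vec = doc2vec_config(embedding_size = 50L, epochs = 10L,
                             min_word_frequency = 5L),
    min_word_frequency = 5L,
    final = list(algorithm = "kmeans", metric = "euclidean", kappa = 5L),
    min_size = 10L, impute_trees = 30L, seed = 3L, ...)
}

# deterministic blobs for clustering tests
make_blobs <- function(n_per, centres, sd = 0.2, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centres)), function(i) {
    matrix(rnorm(n_per * ncol(centres), 0, sd), n_per) +
      matrix(centres[i, ], n_per, ncol(centres), byrow = TRUE)
  }))
  list(x = x, y = rep(seq_len(nrow(centres)), each = n_per))
}

# independent NMI/HS oracle from the contingency-table formulation:
# I = sum_ij p_ij log(p_ij / (p_i q_j)), entropies from the margins
oracle_nmi_hs <- function(y, yhat) {
  tab <- table(y, yhat)
  p <- tab / sum(tab)
  pi <- rowSums(p); qj <- colSums(p)
  terms <- p * log(p / outer(pi, qj))
  i <- sum(terms[p > 0])
  hy <- -sum(pi[pi > 0] * log(pi[pi > 0]))
  hc <- -sum(qj[qj > 0] * log(qj[qj > 0]))
  list(nmi = if (hy + hc > 0) 2 * i / (hy + hc) else 0,
       hs = 1 - (hy - i) / hy)
}

# independent brute-force nearest-centre assignment oracle
oracle_assign <- function(x, centres, metric) {
  vapply(seq_len(nrow(x)), function(i) {
    d <- vapply(seq_len(nrow(centres)), function(k) {
      if (metric == "euclidean") sqrt(sum((x[i, ] - centres[k, ])^2))
      else 1 - sum(x[i, ] * centres[k, ]) /
        (sqrt(sum(x[i, ]^2)) * sqrt(sum(centres[k, ]^2)))
    }, 0)
    which.min(d)
  }, 0L)
}
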