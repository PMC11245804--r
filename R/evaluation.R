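# Cluster quality metrics: normalized mutual information and homogeneity
# against the modality and body-part labels, their harmonic-mean summary
# score S, within-cluster cosine dissimilarity of image and diagnosis
# embeddings (D_I, D_D, D_score), elbow-based model selection across
# extractors, and the post-filters (minimum size, label entropy) applied
# before the labels feed downstream training.

.entropy <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log(p))
}

.cond_entropy <- function(y, yhat) {
  tot <- 0
  for (c in unique(yhat)) {
    idx <- yhat == c
    tot <- tot + sum(idx) / length(y) * .entropy(y[idx])
  }
  tot
}

#' Normalized mutual information between labels and clusters
#'
#' `NMI = 2 I(y, yhat) / (H(y) + H(yhat))` with natural-log entropies (the
#' ratio is base-invariant) and `I = H(y) - H(y | yhat)`. Ranges over
#' `[0, 1]`; 1 iff the clustering matches the labels up to relabelling.
#' When both inputs are constant the value is defined as 0 with a warning.
#'
#' @param y ground-truth label vector.
#' @param yhat cluster assignment vector of the same length.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(y, yhat) {
  assert_that(length(y) == length(yhat), "y and yhat must align")
  hy <- .entropy(y); hc <- .entropy(yhat)
  if (hy + hc == 0) {
    warning("both label and cluster vectors are constant; NMI defined as 0")
    return(0)
  }
  i <- hy - .cond_entropy(y, yhat)
  max(0, min(1, 2 * i / (hy + hc)))
}

#' Homogeneity score of a clustering
#'
#' `HS = 1 - H(y | yhat) / H(y)`: 1 when every cluster contains a single
#' class, 0 when clusters are uninformative about the labels. Requires
#' non-constant labels (`H(y) > 0`).
#'
#' @inheritParams nmi
#' @return HS in `[0, 1]`.
#' @export
hs <- function(y, yhat) {
  assert_that(length(y) == length(yhat), "y and yhat must align")
  hy <- .entropy(y)
  assert_that(hy > 0, "labels are constant (H(y) = 0): HS undefined")
  max(0, min(1, 1 - .cond_entropy(y, yhat) / hy))
}

#' Harmonic-mean summary score of the four homogeneity metrics
#'
#' `S = 4 / (1/HS_B + 1/HS_M + 1/NMI_B + 1/NMI_M)`, defined as 0 when any
#' input is 0 (harmonic-mean limit). The score never exceeds the smallest
#' input.
#'
#' @param hs_b,hs_m,nmi_b,nmi_m component metrics in `[0, 1]`.
#' @return S in `[0, 1]`.
#' @export
score_s <- function(hs_b, hs_m, nmi_b, nmi_m) {
  v <- c(hs_b, hs_m, nmi_b, nmi_m)
  if (any(v == 0)) return(0)
  4 / sum(1 / v)
}

#' Cosine distance between two vectors
#'
#' `1 - u . v / (|u| |v|)`, in `[0, 2]`; zero vectors are rejected.
#'
#' @param u,v numeric vectors of equal length.
#' @return the cosine distance.
#' @export
cosine_distance <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  assert_that(nu > 0 && nv > 0, "cosine distance undefined for zero vectors")
  1 - sum(u * v) / (nu * nv)
}

#' Within-cluster pairwise cosine dissimilarity
#'
#' For each cluster `c` with `k` members, the mean cosine distance over
#' all `u = k (k - 1) / 2` member pairs. The full-pair mean is computed in
#' closed form from the resultant of the unit-normalised member vectors
#' (algebraically identical to enumerating every pair); when `max_pairs`
#' is finite and `u` exceeds it, a seeded uniform sample of `max_pairs`
#' pairs is used instead and the cluster is flagged. Clusters with fewer
#' than two members are excluded from the average and reported.
#'
#' @param embeddings numeric matrix (no zero rows), rows = records.
#' @param cluster 1-based assignment vector covering all rows.
#' @param max_pairs pair budget per cluster; `Inf` (default) means exact.
#' @param seed seed for pair sampling.
#' @return an object of class `dissimilarity_report`: list with
#'   `per_cluster` (cluster, size, n_pairs, mean dissimilarity, pair s.d.
#'   where enumerated, sampled flag), `D` (mean over clusters with >= 2
#'   members), `D_sd` (s.d. over those clusters) and `excluded` (singleton
#'   cluster ids).
#' @export
cluster_dissimilarity <- function(embeddings, cluster, max_pairs = Inf,
                                  seed = 1L) {
  embeddings <- as.matrix(embeddings)
  assert_that(length(cluster) == nrow(embeddings),
              "assignment must cover all records")
  ids <- sort(unique(cluster))
  rows <- list()
  set.seed(seed)
  for (c in ids) {
    members <- which(cluster == c)
    k <- length(members)
    if (k < 2L) {
      rows[[length(rows) + 1L]] <- data.frame(cluster = c, size = k,
                                              n_pairs = 0, mean = NA_real_,
                                              sd = NA_real_, sampled = FALSE)
      next
    }
    u_pairs <- k * (k - 1) / 2
    v <- l2_normalise(embeddings[members, , drop = FALSE])
    if (u_pairs <= max_pairs) {
      # mean over all pairs via the resultant identity:
      # sum_{i != j} v_i . v_j = |sum v|^2 - k
      s <- colSums(v)
      mean_sim <- (sum(s^2) - k) / (k * (k - 1))
      m <- 1 - mean_sim
      sdv <- if (k <= 200L) {
        g <- tcrossprod(v)
        stats::sd(1 - g[upper.tri(g)])
      } else NA_real_
      sampled <- FALSE
    } else {
      i <- sample.int(k, max_pairs, replace = TRUE)
      j <- sample.int(k - 1L, max_pairs, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)
      dists <- 1 - rowSums(v[i, , drop = FALSE] * v[j, , drop = FALSE])
      m <- mean(dists); sdv <- stats::sd(dists)
      sampled <- TRUE
    }
    rows[[length(rows) + 1L]] <- data.frame(cluster = c, size = k,
                                            n_pairs = u_pairs, mean = m,
                                            sd = sdv, sampled = sampled)
  }
  per <- do.call(rbind, rows)
  valid <- per$size >= 2L
  assert_that(any(valid), "all clusters are singletons: dissimilarity undefined")
  structure(list(per_cluster = per, D = mean(per$mean[valid]),
                 D_sd = stats::sd(per$mean[valid]),
                 excluded = per$cluster[!valid]),
            class = "dissimilarity_report")
}

#' @export
print.dissimilarity_report <- function(x, ...) {
  cat("<dissimilarity_report> D = ", sprintf("%.4f", x$D), " +/- ",
      sprintf("%.4f", x$D_sd), " over ", sum(x$per_cluster$size >= 2),
      " clusters", if (length(x$excluded)) paste0(" (", length(x$excluded),
                                                  " singleton excluded)"),
      "\n", sep = "")
  invisible(x)
}

#' Harmonic mean of the image and diagnosis dissimilarities
#'
#' `D_score = 2 D_I D_D / (D_I + D_D)`; lower is better; 0 if either
#' component is 0.
#'
#' @param d_i,d_d mean within-cluster image and diagnosis dissimilarities.
#' @return the harmonic mean.
#' @export
d_score <- function(d_i, d_d) {
  if (d_i == 0 || d_d == 0) return(0)
  2 * d_i * d_d / (d_i + d_d)
}

#' Select the best extractor per source from sweep results
#'
#' Image and diagnosis extractors are ranked by the summary score `S` at
#' their elbow cluster count; tag extractors are ranked by the lowest
#' `D_score` at their elbow, with `D_I`/`D_D` computed from the already
#' selected best image and diagnosis embeddings under the tag clustering.
#'
#' @param sweeps nested list: `sweeps$images`, `sweeps$diagnoses`,
#'   `sweeps$tags`, each a named list of extractor entries with elements
#'   `models` (a [sweep_kappa()] result) and `embeddings`.
#' @param labels named list with `modality` and `body_part` vectors
#'   aligned to the embedding rows.
#' @return list with `report` (one row per extractor: source, extractor,
#'   elbow kappa, metrics) and `winners` (best extractor name per source).
#' @export
select_models <- function(sweeps, labels) {
  assert_that(all(c("images", "diagnoses", "tags") %in% names(sweeps)),
              "sweeps must cover images, diagnoses and tags")
  rows <- list(); winners <- list()
  assignments <- list()
  for (src in c("images", "diagnoses")) {
    best_s <- -Inf
    for (nm in names(sweeps[[src]])) {
      entry <- sweeps[[src]][[nm]]
      assert_that(!is.null(entry$models), sprintf("missing sweep for %s/%s", src, nm))
      grid <- as.numeric(names(entry$models))
      inert <- vapply(entry$models, `[[`, 0, "inertia")
      elbow <- find_elbow(grid, inert)
      m <- entry$models[[elbow$index]]
      yhat <- m$cluster
      met <- list(nmi_b = nmi(labels$body_part, yhat),
                  nmi_m = nmi(labels$modality, yhat),
                  hs_b = hs(labels$body_part, yhat),
                  hs_m = hs(labels$modality, yhat))
      s <- score_s(met$hs_b, met$hs_m, met$nmi_b, met$nmi_m)
      rows[[length(rows) + 1L]] <- data.frame(
        source = src, extractor = nm, kappa = elbow$kappa,
        elbow_flagged = elbow$flagged, nmi_b = met$nmi_b, nmi_m = met$nmi_m,
        hs_b = met$hs_b, hs_m = met$hs_m, s = s,
        d_i = NA_real_, d_d = NA_real_, d_score = NA_real_)
      if (s > best_s) {
        best_s <- s
        winners[[src]] <- nm
        assignments[[src]] <- yhat
      }
    }
  }
  img_emb <- sweeps$images[[winners$images]]$embeddings
  diag_emb <- sweeps$diagnoses[[winners$diagnoses]]$embeddings
  best_d <- Inf
  for (nm in names(sweeps$tags)) {
    entry <- sweeps$tags[[nm]]
    assert_that(!is.null(entry$models), sprintf("missing sweep for tags/%s", nm))
    grid <- as.numeric(names(entry$models))
    inert <- vapply(entry$models, `[[`, 0, "inertia")
    elbow <- find_elbow(grid, inert)
    yhat <- entry$models[[elbow$index]]$cluster
    d_i <- cluster_dissimilarity(img_emb, yhat)$D
    d_d <- cluster_dissimilarity(diag_emb, yhat)$D
    ds <- d_score(d_i, d_d)
    rows[[length(rows) + 1L]] <- data.frame(
      source = "tags", extractor = nm, kappa = elbow$kappa,
      elbow_flagged = elbow$flagged, nmi_b = NA_real_, nmi_m = NA_real_,
      hs_b = NA_real_, hs_m = NA_real_, s = NA_real_,
      d_i = d_i, d_d = d_d, d_score = ds)
    if (ds < best_d) {
      best_d <- ds
      winners$tags <- nm
    }
  }
  list(report = do.call(rbind, rows), winners = winners)
}

#' Filter low-quality clusters before downstream training
#'
#' Removes clusters with fewer than `min_size` members and clusters whose
#' normalised label entropy -- the entropy of the body-part or modality
#' labels within the cluster, divided by the log of that label set's size,
#' so a uniform mixture scores 1 -- reaches `entropy_cutoff` for either
#' label. Surviving clusters are re-indexed densely from 1; removed
#' records get `NA`.
#'
#' @param cluster 1-based assignment vector.
#' @param labels named list with `modality` and `body_part` vectors.
#' @param min_size minimum cluster membership, default 100.
#' @param entropy_cutoff normalised-entropy removal threshold, default 0.9.
#' @return list with `cluster` (filtered, re-indexed, `NA` for removed
#'   records), `kept` (old ids of surviving clusters) and `removal_log`
#'   (cluster, size, entropies, reason).
#' @export
filter_clusters <- function(cluster, labels, min_size = 100L,
                            entropy_cutoff = 0.9) {
  n_bp <- length(unique(labels$body_part))
  n_mod <- length(unique(labels$modality))
  ids <- sort(unique(cluster))
  log_rows <- list()
  kept <- integer(0)
  for (c in ids) {
    idx <- cluster == c
    size <- sum(idx)
    ent_b <- if (n_bp > 1) .entropy(labels$body_part[idx]) / log(n_bp) else 0
    ent_m <- if (n_mod > 1) .entropy(labels$modality[idx]) / log(n_mod) else 0
    reason <- if (size < min_size) "size"
      else if (ent_b >= entropy_cutoff || ent_m >= entropy_cutoff) "entropy"
      else NA_character_
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      cluster = c, size = size, entropy_bodypart = ent_b,
      entropy_modality = ent_m, removed = !is.na(reason),
      reason = if (is.na(reason)) "" else reason)
    if (is.na(reason)) kept <- c(kept, c)
  }
  new_id <- match(cluster, kept)
  list(cluster = new_id, kept = kept,
       removal_log = do.call(rbind, log_rows))
}

#' Oversampling plan to balance surviving clusters
#'
#' Computes per-cluster replication counts bringing every cluster up to
#' the largest cluster's size; the augmentation applied to the replicas is
#' left to downstream training code.
#'
#' @param cluster filtered assignment vector (`NA` entries ignored).
#' @return data frame with `cluster`, `size`, `replicas` and `target`.
#' @export
oversample_plan <- function(cluster) {
  cluster <- cluster[!is.na(cluster)]
  assert_that(length(cluster) > 0, "no records survive filtering")
  sizes <- table(cluster)
  target <- max(sizes)
  data.frame(cluster = as.integer(names(sizes)),
             size = as.integer(sizes),
             replicas = as.integer(target - sizes),
             target = as.integer(target))
}
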