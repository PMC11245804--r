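# Clustering over the embedding spaces: k-means (Euclidean, k-means++
# seeding, Lloyd refinement) and k-medoids (alternating/Voronoi heuristic,
# Euclidean or cosine). Cluster counts are swept over a fixed grid and
# selected with a Kneedle elbow on the inertia curve.

.kpp_init <- function(x, k, metric) {
  n <- nrow(x)
  centres <- integer(k)
  centres[1L] <- sample.int(n, 1L)
  d2 <- distance_matrix(x, x[centres[1L], , drop = FALSE], metric)[, 1L]^2
  for (i in seq_len(k - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centres[i + 1L] <- sample.int(n, 1L, prob = p)
    d_new <- distance_matrix(x, x[centres[i + 1L], , drop = FALSE], metric)[, 1L]^2
    d2 <- pmin(d2, d_new)
  }
  centres
}

.fit_kmeans_once <- function(x, k, max_iter) {
  init <- x[.kpp_init(x, k, "euclidean"), , drop = FALSE]
  tryCatch(stats::kmeans(x, centers = init, iter.max = max_iter,
                         algorithm = "Lloyd"),
           error = function(e) NULL, warning = function(w) {
             suppressWarnings(stats::kmeans(x, centers = init,
                                            iter.max = max_iter,
                                            algorithm = "Lloyd"))
           })
}

.fit_kmedoids_once <- function(x, k, metric, max_iter) {
  med <- .kpp_init(x, k, metric)
  for (it in seq_len(max_iter)) {
    d <- distance_matrix(x, x[med, , drop = FALSE], metric)
    assign <- max.col(-d, ties.method = "first")
    new_med <- med
    for (c in seq_len(k)) {
      members <- which(assign == c)
      if (!length(members)) next   # empty cluster: keep old medoid
      dm <- distance_matrix(x[members, , drop = FALSE],
                            x[members, , drop = FALSE], metric)
      new_med[c] <- members[which.min(rowSums(dm))]
    }
    if (identical(new_med, med)) break
    med <- new_med
  }
  d <- distance_matrix(x, x[med, , drop = FALSE], metric)
  assign <- max.col(-d, ties.method = "first")
  list(medoids = med, cluster = assign,
       inertia = sum(d[cbind(seq_len(nrow(x)), assign)]^2),
       empty = length(unique(assign)) < k)
}

#' Fit a cluster model on an embedding matrix
#'
#' k-means (Euclidean only) uses k-means++ seeding followed by Lloyd
#' iterations, repeated over `n_init` seedings with the lowest-inertia fit
#' kept. k-medoids uses the alternating (Voronoi) heuristic -- assign to
#' the nearest medoid, then re-select each cluster's medoid as the member
#' minimising total within-cluster distance -- under Euclidean or cosine
#' distance. Inertia is the sum of squared distances of records to their
#' nearest centre in the model's metric. If a fit ends with an empty
#' cluster it is re-seeded once and flagged if the problem persists.
#'
#' @param x numeric embedding matrix, rows = records.
#' @param algorithm `"kmeans"` or `"kmedoids"`.
#' @param metric `"euclidean"` or `"cosine"` (cosine distance is 1 minus
#'   cosine similarity); k-means requires Euclidean.
#' @param k number of clusters, `2 <= k <=` records.
#' @param seed integer seed; the fit is deterministic given it.
#' @param n_init independent seedings for k-means.
#' @param max_iter refinement iterations.
#' @return an object of class `radclust_cluster` with `centres` (medoid
#'   rows for k-medoids), `medoid_idx`, `cluster` (training assignment,
#'   1-based), `inertia`, `k`, `algorithm`, `metric`, `seed` and
#'   `empty_cluster` flag.
#' @export
fit_cluster <- function(x, algorithm = c("kmeans", "kmedoids"),
                        metric = c("euclidean", "cosine"), k, seed = 1L,
                        n_init = 10L, max_iter = 100L) {
  algorithm <- match.arg(algorithm)
  metric <- match.arg(metric)
  x <- as.matrix(x)
  assert_that(k >= 2 && k <= nrow(x), "k must lie in [2, records]")
  if (algorithm == "kmeans") {
    assert_that(metric == "euclidean", "k-means supports only Euclidean distance")
  }
  set.seed(seed)
  empty <- FALSE
  if (algorithm == "kmeans") {
    best <- NULL
    for (i in seq_len(n_init)) {
      fit <- .fit_kmeans_once(x, k, max_iter)
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) {  # re-seed once
      best <- .fit_kmeans_once(x, k, max_iter)
      empty <- TRUE
    }
    assert_that(!is.null(best), "k-means failed to produce a valid fit")
    centres <- best$centers
    cluster <- best$cluster
    inertia <- best$tot.withinss
    medoid_idx <- NULL
    empty <- empty || length(unique(cluster)) < k
  } else {
    fit <- .fit_kmedoids_once(x, k, metric, max_iter)
    if (fit$empty) fit <- .fit_kmedoids_once(x, k, metric, max_iter)
    empty <- fit$empty
    centres <- x[fit$medoids, , drop = FALSE]
    cluster <- fit$cluster
    inertia <- fit$inertia
    medoid_idx <- fit$medoids
  }
  rownames(centres) <- NULL
  structure(list(algorithm = algorithm, metric = metric, k = as.integer(k),
                 centres = centres, medoid_idx = medoid_idx,
                 cluster = cluster, inertia = inertia, seed = seed,
                 empty_cluster = empty),
            class = "radclust_cluster")
}

#' Assign records to the nearest cluster centre
#'
#' @param object a `radclust_cluster`.
#' @param newdata embedding matrix.
#' @param ... unused.
#' @return list with `cluster` (1-based index of the nearest centre; ties
#'   broken toward the lowest index) and `distances` (records x k matrix
#'   in the model's metric).
#' @export
predict.radclust_cluster <- function(object, newdata, ...) {
  d <- distance_matrix(as.matrix(newdata), object$centres, object$metric)
  list(cluster = max.col(-d, ties.method = "first"), distances = d)
}

#' @export
print.radclust_cluster <- function(x, ...) {
  cat("<radclust_cluster> ", x$algorithm, " (", x$metric, "), k = ", x$k,
      ", inertia = ", sprintf("%.4g", x$inertia),
      if (x$empty_cluster) " [empty-cluster flag]" else "", "\n", sep = "")
  invisible(x)
}

#' Sweep the number of clusters over a grid
#'
#' Fits one model per grid value. Inertia should be non-increasing in the
#' cluster count up to optimisation noise; violations are recorded in the
#' `monotone_violations` attribute.
#'
#' @inheritParams fit_cluster
#' @param kappa_grid cluster counts to fit, default
#'   `c(5, 10, 15, 20, 25, 30, 40, 50, 75, 100, 150)`.
#' @return named list of `radclust_cluster` models (names = grid values).
#' @export
sweep_kappa <- function(x, algorithm = "kmeans", metric = "euclidean",
                        kappa_grid = c(5L, 10L, 15L, 20L, 25L, 30L, 40L,
                                       50L, 75L, 100L, 150L),
                        seed = 1L, n_init = 10L, max_iter = 100L) {
  kappa_grid <- kappa_grid[kappa_grid < nrow(as.matrix(x))]
  assert_that(length(kappa_grid) >= 1, "no feasible grid value (k < records)")
  models <- lapply(seq_along(kappa_grid), function(i)
    fit_cluster(x, algorithm, metric, kappa_grid[i],
                seed = derive_seed(seed, paste0("kappa", kappa_grid[i])),
                n_init = n_init, max_iter = max_iter))
  names(models) <- kappa_grid
  inert <- vapply(models, `[[`, 0, "inertia")
  viol <- which(diff(inert) > 0)
  if (length(viol)) {
    message("inertia not monotone at kappa = ",
            paste(kappa_grid[viol + 1L], collapse = ", "))
  }
  attr(models, "monotone_violations") <- kappa_grid[viol + 1L]
  models
}

#' Find the elbow of an inertia curve (Kneedle)
#'
#' Normalises the curve to the unit square, flips the decreasing inertia
#' into an increasing concave curve and takes the knee at the maximum of
#' the difference curve (curve minus diagonal). A curve with no curvature
#' (maximum difference numerically zero, e.g. a strictly linear decrease)
#' has no knee; the fallback is the grid value with the largest discrete
#' second difference, flagged in the result.
#'
#' @param kappa_grid increasing cluster counts (at least 3).
#' @param inertias positive inertia values matching the grid.
#' @return list with `kappa` (selected count), `index`, `flagged`
#'   (`TRUE` when the fallback fired) and `differences` (the Kneedle
#'   difference curve).
#' @export
find_elbow <- function(kappa_grid, inertias) {
  assert_that(length(kappa_grid) >= 3 && length(inertias) == length(kappa_grid),
              "need at least 3 grid points with matching inertias")
  assert_that(all(inertias >= 0), "inertias must be non-negative")
  xn <- (kappa_grid - min(kappa_grid)) / diff(range(kappa_grid))
  rng <- diff(range(inertias))
  if (rng == 0) {
    return(list(kappa = kappa_grid[1L], index = 1L, flagged = TRUE,
                differences = numeric(length(kappa_grid))))
  }
  yn <- (inertias - min(inertias)) / rng
  diffs <- (1 - yn) - xn
  if (max(diffs) > 1e-9) {
    idx <- which.max(diffs)
    flagged <- FALSE
  } else {
    second <- diff(diff(inertias))
    idx <- which.max(second) + 1L
    flagged <- TRUE
  }
  list(kappa = kappa_grid[idx], index = idx, flagged = flagged,
       differences = diffs)
}

#' Stability of clustering metrics across repeated runs
#'
#' Refits the same configuration under `runs` distinct seeds and reports
#' the per-run evaluation metrics with their mean and standard deviation,
#' quantifying sensitivity to centroid initialisation.
#'
#' @inheritParams fit_cluster
#' @param labels named list of ground-truth label vectors (e.g.
#'   `list(modality = ..., body_part = ...)`) used for NMI/HS.
#' @param runs number of independent runs, default 11.
#' @return list with `runs` (data frame of per-run metrics incl. inertia)
#'   and `summary` (mean and s.d. per metric).
#' @export
stability_check <- function(x, algorithm = "kmeans", metric = "euclidean",
                            k, labels, runs = 11L, seed = 1L,
                            n_init = 10L) {
  rows <- lapply(seq_len(runs), function(r) {
    m <- fit_cluster(x, algorithm, metric, k,
                     seed = derive_seed(seed, paste0("run", r)),
                     n_init = n_init)
    out <- list(run = r, inertia = m$inertia)
    for (nm in names(labels)) {
      out[[paste0("nmi_", nm)]] <- nmi(labels[[nm]], m$cluster)
      out[[paste0("hs_", nm)]] <- hs(labels[[nm]], m$cluster)
    }
    as.data.frame(out)
  })
  runs_df <- do.call(rbind, rows)
  metr <- setdiff(names(runs_df), "run")
  summ <- data.frame(metric = metr,
                     mean = vapply(runs_df[metr], mean, 0),
                     sd = vapply(runs_df[metr], stats::sd, 0))
  list(runs = runs_df, summary = summ)
}
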