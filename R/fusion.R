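# Multimodal fusion: per-source embeddings are combined into one flat
# vector per record by (a) direct concatenation, (b) concatenation of
# min-max-normalised distances to each source's cluster centres
# ("clusterdists"), or (c) softmax-of-negative-distance cluster
# probabilities ("clusterprobs"). Normalisation constants are fitted on the
# training subset per source and clipped at transform time.

.check_parts <- function(parts) {
  assert_that(is.list(parts) && length(parts) >= 1, "parts must be a list")
  n <- vapply(parts, nrow, 0L)
  assert_that(length(unique(n)) == 1L,
              "all parts must cover the same records (equal row counts)")
  if (is.null(names(parts))) names(parts) <- paste0("source", seq_along(parts))
  parts
}

.with_spans <- function(mat, parts_ncol, method, extra = NULL) {
  ends <- cumsum(parts_ncol)
  starts <- c(1L, head(ends, -1L) + 1L)
  spans <- Map(function(s, e) c(start = s, end = e), starts, ends)
  names(spans) <- names(parts_ncol)
  structure(mat, method = method, component_spans = spans, extra = extra)
}

#' Fuse per-source embeddings by concatenation
#'
#' Concatenates the sources' embedding vectors in the given order
#' (conventionally diagnosis, tags, image) into one flat vector per record.
#'
#' @param parts named, ordered list of embedding matrices with aligned rows.
#' @return fused matrix with attributes `method` and `component_spans`
#'   (per-source column ranges).
#' @export
fuse_embeddings <- function(parts) {
  parts <- .check_parts(parts)
  mat <- do.call(cbind, parts)
  .with_spans(mat, vapply(parts, ncol, 0L), "embeddings")
}

# per-source distances to centres plus fitted/applied normalisers
.source_dists <- function(parts, models, normalisers) {
  fitted <- is.null(normalisers)
  if (fitted) normalisers <- vector("list", length(parts))
  dists <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    m <- models[[i]]
    assert_that(inherits(m, "radclust_cluster"), "unfitted cluster model")
    d <- distance_matrix(parts[[i]], m$centres, m$metric)
    if (fitted) normalisers[[i]] <- fit_minmax(as.vector(d))
    dists[[i]] <- apply_minmax(d, normalisers[[i]])
  }
  names(normalisers) <- names(parts)
  list(dists = dists, normalisers = normalisers)
}

#' Fuse embeddings through cluster-space distances
#'
#' For each source, the distances from the record to that source's fitted
#' cluster centres (in the source's own metric) are min-max normalised to
#' `[0, 1]` -- constants fitted on the training subset per source -- and
#' the per-source distance blocks are concatenated; the fused length is the
#' sum of the sources' cluster counts.
#'
#' @param parts named, ordered list of embedding matrices.
#' @param models list of fitted [fit_cluster()] models, one per source.
#' @param normalisers per-source min-max constants from a previous
#'   (training) call; `NULL` fits them on `parts`.
#' @return fused matrix with attributes `method`, `component_spans` and
#'   `normalisers`.
#' @export
fuse_clusterdists <- function(parts, models, normalisers = NULL) {
  parts <- .check_parts(parts)
  sd <- .source_dists(parts, models, normalisers)
  mat <- do.call(cbind, sd$dists)
  out <- .with_spans(mat, vapply(sd$dists, ncol, 0L), "clusterdists")
  attr(out, "normalisers") <- sd$normalisers
  out
}

#' Fuse embeddings through cluster assignment probabilities
#'
#' As [fuse_clusterdists()], but each source's distance block is converted
#' to a probability block with a softmax over negated distances,
#' `p_c = exp(-d_c) / sum_j exp(-d_j)`, assigning higher probability to
#' nearer centres. Distances are the `[0, 1]`-normalised ones by default,
#' which keeps the softmax away from saturation and the sources on a
#' common scale; set `use_normalised = FALSE` to feed raw distances.
#'
#' @inheritParams fuse_clusterdists
#' @param use_normalised feed normalised (default) or raw distances to the
#'   softmax.
#' @return fused probability matrix; each source block sums to 1 per row.
#' @export
fuse_clusterprobs <- function(parts, models, normalisers = NULL,
                              use_normalised = TRUE) {
  parts <- .check_parts(parts)
  if (use_normalised) {
    sd <- .source_dists(parts, models, normalisers)
    dists <- sd$dists
    norms <- sd$normalisers
  } else {
    dists <- lapply(seq_along(parts), function(i)
      distance_matrix(parts[[i]], models[[i]]$centres, models[[i]]$metric))
    norms <- NULL
  }
  probs <- lapply(dists, function(d) {
    e <- exp(-d)
    e / rowSums(e)
  })
  mat <- do.call(cbind, probs)
  out <- .with_spans(mat, vapply(probs, ncol, 0L), "clusterprobs")
  attr(out, "normalisers") <- norms
  out
}
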