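# Paragraph-vector document embeddings (doc2vec), trained from scratch with
# negative sampling. PV-DM predicts each word from the paragraph vector
# averaged with the input vectors of the context words inside the window;
# PV-DBOW predicts the document's words from the paragraph vector alone.
# Single-worker updates in document order make training deterministic given
# the seed.

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Configuration for paragraph-vector training
#'
#' Defaults follow the selected diagnosis extractor: PV-DBOW with
#' embedding size 1000, window 7, 50 epochs, minimum word frequency 50.
#'
#' @param mode `"PV-DBOW"` or `"PV-DM"`.
#' @param embedding_size paragraph vector length.
#' @param window context half-width (PV-DM only).
#' @param epochs training epochs.
#' @param min_word_frequency corpus admission threshold.
#' @param negative negative samples per target word.
#' @param alpha,min_alpha initial and final learning rate (linear decay
#'   across epochs).
#' @param seed integer seed.
#' @return an object of class `doc2vec_config`.
#' @export
doc2vec_config <- function(mode = c("PV-DBOW", "PV-DM"),
                           embedding_size = 1000L, window = 7L,
                           epochs = 50L, min_word_frequency = 50L,
                           negative = 5L, alpha = 0.025, min_alpha = 1e-4,
                           seed = 1L) {
  mode <- match.arg(mode)
  assert_that(embedding_size >= 1 && window >= 1 && epochs >= 1,
              "embedding_size, window and epochs must be positive")
  structure(as.list(environment()), class = "doc2vec_config")
}

# negative-sampling table: unigram^(3/4) cumulative distribution
.neg_table <- function(counts) {
  p <- counts^0.75
  cumsum(p / sum(p))
}

# core SGNS sweep over documents; updates doc vectors (and, for PV-DM,
# input word vectors) in place and returns the modified matrices.
# When freeze = TRUE only doc vectors learn (inference mode).
.d2v_sweep <- function(doc_ids, dmat, win_in, wout, cfg, cum, freeze) {
  n_docs <- length(doc_ids)
  v <- ncol(wout %||% matrix(0, 1, 1))
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$alpha - (cfg$alpha - cfg$min_alpha) * (epoch - 1) /
      max(1, cfg$epochs - 1)
    for (d in seq_len(n_docs)) {
      ids <- doc_ids[[d]]
      len <- length(ids)
      if (!len) next
      for (t in seq_len(len)) {
        target <- ids[t]
        negs <- findInterval(stats::runif(cfg$negative), cum) + 1L
        js <- c(target, negs)
        labels <- c(1, numeric(cfg$negative))
        if (cfg$mode == "PV-DBOW") {
          vec <- dmat[d, ]
          u <- wout[js, , drop = FALSE]
          g <- (labels - .sigmoid(u %*% vec)) * lr
          dmat[d, ] <- vec + crossprod(u, g)
          if (!freeze) wout[js, ] <- u + g %*% rbind(vec)
        } else {
          lo <- max(1L, t - cfg$window); hi <- min(len, t + cfg$window)
          ctx <- ids[setdiff(lo:hi, t)]
          k <- length(ctx) + 1L
          vec <- (dmat[d, ] + if (length(ctx))
            colSums(win_in[ctx, , drop = FALSE]) else 0) / k
          u <- wout[js, , drop = FALSE]
          g <- (labels - .sigmoid(u %*% vec)) * lr
          dvec <- as.vector(crossprod(u, g)) / k
          dmat[d, ] <- dmat[d, ] + dvec
          if (!freeze) {
            if (length(ctx)) {
              win_in[ctx, ] <- sweep(win_in[ctx, , drop = FALSE], 2, dvec, "+")
            }
            wout[js, ] <- u + g %*% rbind(vec)
          }
        }
      }
    }
  }
  list(dmat = dmat, win_in = win_in, wout = wout)
}

#' Fit a paragraph-vector (doc2vec) extractor
#'
#' Trains paragraph vectors on the training documents with negative
#' sampling. The corpus is built at `cfg$min_word_frequency` unless
#' supplied; out-of-vocabulary stems are dropped from every document.
#'
#' @param docs list of stem vectors (training subset).
#' @param cfg a [doc2vec_config()].
#' @param corpus optional pre-built [build_corpus()] result.
#' @return an object of class `radclust_doc2vec`; `fit$doc_vectors` holds
#'   the training-document embeddings and `predict(fit, newdocs)` infers
#'   vectors for unseen documents with frozen word weights.
#' @export
fit_doc2vec <- function(docs, cfg = doc2vec_config(), corpus = NULL) {
  stopifnot(inherits(cfg, "doc2vec_config"))
  if (is.null(corpus)) corpus <- build_corpus(docs, cfg$min_word_frequency)
  vocab <- corpus$vocabulary
  doc_ids <- lapply(docs, function(s) {
    i <- match(s, vocab); i[!is.na(i)]
  })
  v <- length(vocab); d <- cfg$embedding_size
  set.seed(cfg$seed)
  dmat <- matrix((stats::runif(length(docs) * d) - 0.5) / d, length(docs), d)
  win_in <- if (cfg$mode == "PV-DM")
    matrix((stats::runif(v * d) - 0.5) / d, v, d) else NULL
  wout <- matrix(0, v, d)
  cum <- .neg_table(corpus$stem_counts)
  res <- .d2v_sweep(doc_ids, dmat, win_in, wout, cfg, cum, freeze = FALSE)
  structure(list(doc_vectors = res$dmat, word_out = res$wout,
                 word_in = res$win_in, corpus = corpus, cfg = cfg,
                 embedding_size = d),
            class = "radclust_doc2vec")
}

#' Infer paragraph vectors for unseen documents
#'
#' Freezes the trained word weights and runs the same update schedule on
#' fresh document vectors. Deterministic given `seed`.
#'
#' @param object a `radclust_doc2vec`.
#' @param newdocs list of stem vectors.
#' @param seed seed for negative sampling and initialisation.
#' @param ... unused.
#' @return embedding matrix, one row per document.
#' @export
predict.radclust_doc2vec <- function(object, newdocs, seed = 1L, ...) {
  cfg <- object$cfg
  vocab <- object$corpus$vocabulary
  doc_ids <- lapply(newdocs, function(s) {
    i <- match(s, vocab); i[!is.na(i)]
  })
  d <- object$embedding_size
  set.seed(seed)
  dmat <- matrix((stats::runif(length(newdocs) * d) - 0.5) / d,
                 length(newdocs), d)
  cum <- .neg_table(object$corpus$stem_counts)
  res <- .d2v_sweep(doc_ids, dmat, object$word_in, object$word_out, cfg,
                    cum, freeze = TRUE)
  res$dmat
}

#' @export
print.radclust_doc2vec <- function(x, ...) {
  cat("<radclust_doc2vec> ", x$cfg$mode, ", ", nrow(x$doc_vectors),
      " documents, embedding size ", x$embedding_size, ", vocabulary ",
      length(x$corpus$vocabulary), "\n", sep = "")
  invisible(x)
}
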