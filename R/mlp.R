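# Dense autoencoder for encoded tag matrices: three ReLU encoder layers, a
# linear bottleneck, a fully symmetric decoder, MSE objective, Adam updates
# in mini-batches, early stopping on the monitored loss. Written directly in
# base R matrix algebra; sizes here (hundreds of units, tens of features)
# are comfortably within BLAS territory.

.relu <- function(x) (x > 0) * x

.init_dense <- function(sizes, seed) {
  set.seed(seed)
  lapply(seq_len(length(sizes) - 1L), function(i) {
    fan_in <- sizes[i]
    list(W = matrix(stats::rnorm(fan_in * sizes[i + 1L], 0,
                                 sqrt(2 / fan_in)), fan_in, sizes[i + 1L]),
         b = rep(0, sizes[i + 1L]))
  })
}

.adam_state <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

# forward pass; activations[[i]] is input to layer i; ReLU on all layers
# except the bottleneck and the final reconstruction, which stay linear
.mlp_forward <- function(x, params, linear_idx) {
  acts <- vector("list", length(params) + 1L)
  acts[[1L]] <- x
  for (i in seq_along(params)) {
    z <- sweep(acts[[i]] %*% params[[i]]$W, 2, params[[i]]$b, "+")
    acts[[i + 1L]] <- if (i %in% linear_idx) z else .relu(z)
  }
  acts
}

.mlp_loss <- function(x, params, linear_idx) {
  acts <- .mlp_forward(x, params, linear_idx)
  mean((acts[[length(acts)]] - x)^2)
}

# one Adam mini-batch step on the autoencoder MSE; returns updated params/state
.mlp_step <- function(xb, params, state, linear_idx, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  acts <- .mlp_forward(xb, params, linear_idx)
  n <- nrow(xb)
  delta <- 2 * (acts[[length(acts)]] - xb) / (n * ncol(xb))
  for (i in rev(seq_along(params))) {
    if (!(i %in% linear_idx)) delta <- delta * (acts[[i + 1L]] > 0)
    gW <- crossprod(acts[[i]], delta)
    gb <- colSums(delta)
    if (i > 1L) delta <- tcrossprod(delta, params[[i]]$W)
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * gW
    s$vW <- beta2 * s$vW + (1 - beta2) * gW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * gb
    s$vb <- beta2 * s$vb + (1 - beta2) * gb^2
    corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
    params[[i]]$W <- params[[i]]$W - lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
    params[[i]]$b <- params[[i]]$b - lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    state[[i]] <- s
  }
  list(params = params, state = state)
}

#' Configuration for the dense tag autoencoder
#'
#' Defaults are the selected architecture for tag embeddings: encoder
#' 512 -> 200 -> 125 with ReLU activations, a 32-unit bottleneck, learning
#' rate 1e-2, mini-batches of 32, at most 100 epochs with early stopping
#' after 5 epochs without improvement.
#'
#' @param layer_sizes three strictly decreasing encoder layer widths.
#' @param bottleneck embedding size; must be below the last layer width.
#' @param learning_rate positive Adam step size.
#' @param max_epochs,batch_size,patience training schedule.
#' @param seed integer seed for weight initialisation and batch order.
#' @return an object of class `tag_ae_config`.
#' @export
tag_ae_config <- function(layer_sizes = c(512L, 200L, 125L), bottleneck = 32L,
                          learning_rate = 1e-2, max_epochs = 100L,
                          batch_size = 32L, patience = 5L, seed = 1L) {
  assert_that(length(layer_sizes) == 3L && all(diff(layer_sizes) < 0),
              "layer_sizes must be three strictly decreasing widths")
  assert_that(bottleneck < layer_sizes[3L],
              "bottleneck must be smaller than the last layer")
  assert_that(learning_rate > 0, "learning_rate must be positive")
  structure(as.list(environment()), class = "tag_ae_config")
}

#' Fit the dense autoencoder tag feature extractor
#'
#' Trains a symmetric dense autoencoder on the encoded tag matrix and
#' returns the encoder as a feature extractor: `predict()` on new encoded
#' tables yields `cfg$bottleneck`-length embeddings. Training minimises the
#' mean squared reconstruction error with Adam; the monitored loss is the
#' validation loss when `x_val` is supplied, otherwise the training-epoch
#' loss, with early stopping at `cfg$patience` and the best checkpoint kept.
#'
#' @param x numeric training matrix from [encode_tags()] (finite values).
#' @param cfg a [tag_ae_config()].
#' @param x_val optional validation matrix for loss monitoring.
#' @return an object of class `radclust_tag_ae` with the training history;
#'   use `predict(fit, newdata)` for embeddings.
#' @export
fit_tag_autoencoder <- function(x, cfg = tag_ae_config(), x_val = NULL) {
  stopifnot(inherits(cfg, "tag_ae_config"))
  x <- as.matrix(x)
  assert_that(all(is.finite(x)), "training matrix must be finite")
  p <- ncol(x)
  sizes <- c(p, cfg$layer_sizes, cfg$bottleneck,
             rev(cfg$layer_sizes), p)
  n_enc <- length(cfg$layer_sizes) + 1L        # layers up to the bottleneck
  linear_idx <- c(n_enc, length(sizes) - 1L)   # bottleneck + reconstruction
  params <- .init_dense(sizes, cfg$seed)
  state <- .adam_state(params)
  monitor <- if (is.null(x_val)) x else x_val

  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- numeric(0)
  t <- 0L
  set.seed(cfg$seed + 1L)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(nrow(x))
    for (start in seq(1L, nrow(x), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, nrow(x))]
      t <- t + 1L
      upd <- .mlp_step(x[idx, , drop = FALSE], params, state, linear_idx,
                       cfg$learning_rate, t)
      params <- upd$params; state <- upd$state
    }
    loss <- .mlp_loss(monitor, params, linear_idx)
    assert_that(is.finite(loss), "non-finite loss: training diverged")
    history <- c(history, loss)
    if (loss < best$loss) best <- list(loss = loss, params = params, epoch = epoch)
    if (epoch - best$epoch >= cfg$patience) break
  }
  structure(list(params = best$params, n_encoder_layers = n_enc,
                 linear_idx = linear_idx, cfg = cfg, history = history,
                 best_loss = best$loss, input_dim = p,
                 embedding_size = cfg$bottleneck),
            class = "radclust_tag_ae")
}

#' Embed encoded tag rows with a fitted autoencoder
#'
#' @param object a `radclust_tag_ae`.
#' @param newdata numeric matrix with the training columns.
#' @param type `"encode"` (bottleneck embedding, default) or
#'   `"reconstruct"`.
#' @param ... unused.
#' @return embedding (or reconstruction) matrix.
#' @export
predict.radclust_tag_ae <- function(object, newdata,
                                    type = c("encode", "reconstruct"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  acts <- .mlp_forward(x, object$params, object$linear_idx)
  if (type == "encode") acts[[object$n_encoder_layers + 1L]]
  else acts[[length(acts)]]
}

#' @export
print.radclust_tag_ae <- function(x, ...) {
  cat("<radclust_tag_ae> ", x$input_dim, " -> ",
      paste(x$cfg$layer_sizes, collapse = " -> "), " -> ",
      x$embedding_size, "; best monitored MSE ",
      sprintf("%.5g", x$best_loss), " after ", length(x$history),
      " epochs\n", sep = "")
  invisible(x)
}
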