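# Convolutional autoencoder for exported images, in base R matrix algebra.
# Convolutions are im2col matrix products; layout throughout is
# (H, W, N, C) so a (H*W*N, F) product result reshapes without permutation.
# Encoder: [3x3 conv -> ReLU -> 2x2 max-pool] per filter count, then a
# final 3x3 conv (ReLU) whose flattened feature map is the embedding.
# Decoder mirrors the encoder with nearest-neighbour upsampling, ending in
# a linear 3x3 conv back to one channel. MSE objective, Adam updates.

.pad1 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- x
  out
}

# A 'same' 3x3 convolution is evaluated as the sum over the nine kernel
# offsets of a shifted-input slab times the offset's (C_in x F) weight
# block -- nine GEMMs, no im2col buffer. Weight rows are ordered with the
# kernel row fastest, then kernel column, then input channel.

# row indices of weight block for offset (dy, dx), dy/dx in 0..2
.offset_rows <- function(dy, dx, in_ch) {
  (seq_len(in_ch) - 1L) * 9L + dx * 3L + dy + 1L
}

# shifted slab of the padded input as an (H*W*N, C) matrix
.slab <- function(xp, dy, dx, d) {
  s <- xp[dy + seq_len(d[1]), dx + seq_len(d[2]), , , drop = FALSE]
  dim(s) <- c(d[1] * d[2] * d[3], d[4])
  s
}

# y(H*W*N, F) = sum over offsets of slab %*% W_block
.conv_apply <- function(xp, d, W, b, relu = TRUE) {
  f <- ncol(W)
  y <- matrix(rep(b, each = d[1] * d[2] * d[3]), ncol = f)
  for (dx in 0:2) for (dy in 0:2) {
    y <- y + .slab(xp, dy, dx, d) %*% W[.offset_rows(dy, dx, d[4]), ,
                                        drop = FALSE]
  }
  if (relu) y <- .relu(y)
  y
}

# gradient wrt the input of a 'same' 3x3 correlation: another 'same' 3x3
# correlation of the output gradient with spatially flipped kernels and
# the channel roles swapped
.flip_weights <- function(W, in_ch) {
  f <- ncol(W)
  wa <- array(W, c(3L, 3L, in_ch, f))
  wrot <- wa[3:1, 3:1, , , drop = FALSE]
  matrix(aperm(wrot, c(1, 2, 4, 3)), 9L * f, in_ch)
}

.conv_forward <- function(x, W, b, relu = TRUE) {
  d <- dim(x)
  xp <- .pad1(x)
  y <- .conv_apply(xp, d, W, b, relu)
  list(out = array(y, c(d[1], d[2], d[3], ncol(W))), xp = xp)
}

.conv_backward <- function(dy, cache_xp, x_dim, W, out, relu = TRUE) {
  f <- dim(dy)[4]
  dym <- matrix(dy, ncol = f)
  if (relu) dym <- dym * (matrix(out, ncol = f) > 0)
  gW <- matrix(0, nrow(W), f)
  for (dx in 0:2) for (dy_ in 0:2) {
    gW[.offset_rows(dy_, dx, x_dim[4]), ] <-
      crossprod(.slab(cache_xp, dy_, dx, x_dim), dym)
  }
  gb <- colSums(dym)
  dy_arr <- array(dym, c(x_dim[1], x_dim[2], x_dim[3], f))
  dx_m <- .conv_apply(.pad1(dy_arr),
                      c(x_dim[1], x_dim[2], x_dim[3], f),
                      .flip_weights(W, x_dim[4]), numeric(x_dim[4]),
                      relu = FALSE)
  list(dx = array(dx_m, x_dim), gW = gW, gb = gb)
}

.maxpool2 <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  a <- x[i1, j1, , , drop = FALSE]; b <- x[i2, j1, , , drop = FALSE]
  cc <- x[i1, j2, , , drop = FALSE]; e <- x[i2, j2, , , drop = FALSE]
  pmax(a, b, cc, e)
}

.maxpool2_backward <- function(dy, x, y) {
  d <- dim(x)
  dx <- array(0, d)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  for (oi in 1:2) for (oj in 1:2) {
    ii <- if (oi == 1) i1 else i2
    jj <- if (oj == 1) j1 else j2
    mask <- (x[ii, jj, , , drop = FALSE] == y)
    dx[ii, jj, , ] <- mask * dy
  }
  dx
}

.upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

.upsample2_backward <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  dy[i1, j1, , , drop = FALSE] + dy[i2, j1, , , drop = FALSE] +
    dy[i1, j2, , , drop = FALSE] + dy[i2, j2, , , drop = FALSE]
}

#' Configuration for the convolutional image autoencoder
#'
#' Defaults follow the selected image extractor: four 3x3 convolution
#' blocks of 64, 128, 256 and 512 filters, each with ReLU and 2x2
#' max-pooling, a final 1024-filter convolution whose flattened feature map
#' is the embedding (65,536 values for 128 x 128 input), a mirrored
#' decoder, Adam at learning rate 1e-6, mini-batches of 32, at most 40
#' epochs with validation checked twice per epoch and early stopping after
#' 5 checks without improvement. Smaller filter stacks make desk-scale
#' training practical and are configured the same way.
#'
#' @param encoder_filters filter counts of the pooled encoder blocks.
#' @param final_filters filters of the last (embedding) convolution.
#' @param learning_rate,max_epochs,batch_size,patience training schedule;
#'   `patience` counts validation checks (two per epoch).
#' @param train_sample optional cap on the number of training images; when
#'   set, a seeded subsample of the training set is used for the gradient
#'   updates (the extractor still embeds every image).
#' @param seed integer seed.
#' @return an object of class `cae_config`.
#' @export
cae_config <- function(encoder_filters = c(64L, 128L, 256L, 512L),
                       final_filters = 1024L, learning_rate = 1e-6,
                       max_epochs = 40L, batch_size = 32L, patience = 5L,
                       train_sample = NULL, seed = 1L) {
  assert_that(length(encoder_filters) >= 1 && all(encoder_filters >= 1),
              "encoder_filters must be positive counts")
  assert_that(learning_rate > 0, "learning_rate must be positive")
  structure(as.list(environment()), class = "cae_config")
}

.cae_init <- function(cfg, side) {
  chans <- c(1L, cfg$encoder_filters)
  layers <- list()
  for (i in seq_along(cfg$encoder_filters)) {
    layers[[length(layers) + 1L]] <-
      list(kind = "conv", relu = TRUE, in_ch = chans[i], out_ch = chans[i + 1L])
    layers[[length(layers) + 1L]] <- list(kind = "pool")
  }
  layers[[length(layers) + 1L]] <-
    list(kind = "conv", relu = TRUE, in_ch = tail(chans, 1L),
         out_ch = cfg$final_filters)
  enc_len <- length(layers)
  dec_chans <- c(cfg$final_filters, rev(cfg$encoder_filters))
  layers[[length(layers) + 1L]] <-
    list(kind = "conv", relu = TRUE, in_ch = dec_chans[1L], out_ch = dec_chans[2L])
  for (i in seq_along(cfg$encoder_filters)) {
    layers[[length(layers) + 1L]] <- list(kind = "up")
    last <- i == length(cfg$encoder_filters)
    layers[[length(layers) + 1L]] <-
      list(kind = "conv", relu = !last, in_ch = dec_chans[i + 1L],
           out_ch = if (last) 1L else dec_chans[i + 2L])
  }
  set.seed(cfg$seed)
  for (i in seq_along(layers)) {
    if (layers[[i]]$kind != "conv") next
    fan_in <- 9L * layers[[i]]$in_ch
    layers[[i]]$W <- matrix(stats::rnorm(fan_in * layers[[i]]$out_ch, 0,
                                         sqrt(2 / fan_in)),
                            fan_in, layers[[i]]$out_ch)
    layers[[i]]$b <- rep(0, layers[[i]]$out_ch)
  }
  fmap <- side %/% 2L^length(cfg$encoder_filters)
  list(layers = layers, enc_len = enc_len, side = side, fmap = fmap)
}

.cae_forward <- function(x, net, upto = length(net$layers),
                         keep = TRUE) {
  acts <- if (keep) list(x) else NULL
  caches <- if (keep) vector("list", upto) else NULL
  cur <- x
  for (i in seq_len(upto)) {
    ly <- net$layers[[i]]
    if (ly$kind == "conv") {
      r <- .conv_forward(cur, ly$W, ly$b, relu = ly$relu)
      if (keep) caches[[i]] <- r$xp
      cur <- r$out
    } else if (ly$kind == "pool") {
      cur <- .maxpool2(cur)
    } else {
      cur <- .upsample2(cur)
    }
    if (keep) acts[[i + 1L]] <- cur
  }
  if (keep) list(acts = acts, caches = caches) else cur
}

.cae_loss <- function(x, net) {
  out <- .cae_forward(x, net, keep = FALSE)
  mean((out - x)^2)
}

.cae_step <- function(x, net, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  f <- .cae_forward(x, net)
  acts <- f$acts
  recon <- acts[[length(acts)]]
  delta <- 2 * (recon - x) / length(x)
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    if (ly$kind == "conv") {
      bk <- .conv_backward(delta, f$caches[[i]], dim(acts[[i]]), ly$W,
                           acts[[i + 1L]], relu = ly$relu)
      s <- state[[i]]
      s$mW <- beta1 * s$mW + (1 - beta1) * bk$gW
      s$vW <- beta2 * s$vW + (1 - beta2) * bk$gW^2
      s$mb <- beta1 * s$mb + (1 - beta1) * bk$gb
      s$vb <- beta2 * s$vb + (1 - beta2) * bk$gb^2
      corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
      net$layers[[i]]$W <- ly$W - lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
      net$layers[[i]]$b <- ly$b - lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
      state[[i]] <- s
      delta <- bk$dx
    } else if (ly$kind == "pool") {
      delta <- .maxpool2_backward(delta, acts[[i]], acts[[i + 1L]])
    } else {
      delta <- .upsample2_backward(delta)
    }
  }
  list(net = net, state = state)
}

# rows of an export matrix -> (side, side, N, 1) array on [0, 1]
.rows_to_batch <- function(rows, side) {
  array(t(rows) / 255, c(side, side, nrow(rows), 1L))
}

#' Fit the convolutional autoencoder image feature extractor
#'
#' Trains the mirrored convolutional autoencoder on exported images with
#' mean squared reconstruction error and Adam. When a validation set is
#' given, its loss is evaluated twice per epoch (mid-epoch and end) and
#' drives early stopping, otherwise the training loss once per epoch; the
#' best checkpoint is kept. `predict()` returns the flattened final
#' encoder feature map per image.
#'
#' @param images matrix of exported images, one flattened `side^2` row per
#'   record (see [export_images()]), values in `[0, 255]`.
#' @param cfg a [cae_config()].
#' @param images_val optional validation matrix in the same layout.
#' @param side image side length (rows must have `side^2` entries).
#' @return an object of class `radclust_cae`.
#' @export
fit_cae <- function(images, cfg = cae_config(), images_val = NULL,
                    side = 128L) {
  stopifnot(inherits(cfg, "cae_config"))
  images <- as.matrix(images)
  assert_that(ncol(images) == side^2, "rows must be flattened side x side images")
  if (!is.null(cfg$train_sample) && nrow(images) > cfg$train_sample) {
    set.seed(cfg$seed + 2L)
    images <- images[sample(nrow(images), cfg$train_sample), , drop = FALSE]
  }
  assert_that(side %% 2L^length(cfg$encoder_filters) == 0L,
              "side must be divisible by 2^(number of pooled blocks)")
  net <- .cae_init(cfg, side)
  state <- lapply(net$layers, function(ly) {
    if (ly$kind != "conv") return(NULL)
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
  })
  monitor <- function(n) {
    rows <- if (is.null(images_val)) images else images_val
    # loss on a bounded monitor sample keeps checks cheap and deterministic
    take <- seq_len(min(nrow(rows), 256L))
    .cae_loss(.rows_to_batch(rows[take, , drop = FALSE], side), n)
  }
  best <- list(loss = Inf, layers = net$layers, check = 0L)
  history <- numeric(0)
  t <- 0L; check <- 0L
  set.seed(cfg$seed + 1L)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(nrow(images))
    starts <- seq(1L, nrow(images), by = cfg$batch_size)
    half <- starts[ceiling(length(starts) / 2)]
    for (start in starts) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, nrow(images))]
      t <- t + 1L
      upd <- .cae_step(.rows_to_batch(images[idx, , drop = FALSE], side),
                       net, state, cfg$learning_rate, t)
      net <- upd$net; state <- upd$state
      at_check <- (!is.null(images_val) && start == half) || start == tail(starts, 1L)
      if (at_check) {
        loss <- monitor(net)
        assert_that(is.finite(loss), "non-finite loss: training diverged")
        check <- check + 1L
        history <- c(history, loss)
        if (loss < best$loss) best <- list(loss = loss, layers = net$layers,
                                           check = check)
        if (check - best$check >= cfg$patience) {
          net$layers <- best$layers
          return(.cae_result(net, cfg, history, best$loss))
        }
      }
    }
  }
  net$layers <- best$layers
  .cae_result(net, cfg, history, best$loss)
}

.cae_result <- function(net, cfg, history, best_loss) {
  structure(list(net = net, cfg = cfg, history = history,
                 best_loss = best_loss,
                 embedding_size = net$fmap^2 * cfg$final_filters),
            class = "radclust_cae")
}

#' Embed exported images with a fitted convolutional autoencoder
#'
#' @param object a `radclust_cae`.
#' @param newdata export matrix (flattened `side^2` rows).
#' @param type `"encode"` (flattened final feature map, default) or
#'   `"reconstruct"`.
#' @param batch_size images per forward batch.
#' @param ... unused.
#' @return matrix with one row per image.
#' @export
predict.radclust_cae <- function(object, newdata, type = c("encode",
                                                           "reconstruct"),
                                 batch_size = 64L, ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  net <- object$net
  upto <- if (type == "encode") net$enc_len else length(net$layers)
  out <- NULL
  for (start in seq(1L, nrow(newdata), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, nrow(newdata))
    x <- .rows_to_batch(newdata[idx, , drop = FALSE], net$side)
    last <- .cae_forward(x, net, upto = upto, keep = FALSE)
    d <- dim(last)
    flat <- matrix(aperm(last, c(1, 2, 4, 3)), nrow = d[3], byrow = TRUE)
    if (is.null(out)) out <- matrix(0, nrow(newdata), ncol(flat))
    out[idx, ] <- flat
  }
  rownames(out) <- rownames(newdata)
  out
}

#' @export
print.radclust_cae <- function(x, ...) {
  cat("<radclust_cae> filters ",
      paste(x$cfg$encoder_filters, collapse = "-"), " + ",
      x$cfg$final_filters, "; embedding length ", x$embedding_size,
      "; best monitored MSE ", sprintf("%.5g", x$best_loss), "\n", sep = "")
  invisible(x)
}

#' Reduce image embeddings with PCA
#'
#' @param embeddings matrix of flattened autoencoder features.
#' @param n_components target dimensionality, default 500.
#' @param solver PCA solver, default `"randomised"`.
#' @param seed seed for the randomized solver.
#' @return score matrix with the fitted `radclust_pca` attached as
#'   attribute `"extractor"` for application to new data.
#' @export
reduce_pca <- function(embeddings, n_components = 500L,
                       solver = "randomised", seed = 1L) {
  fit <- fit_pca(embeddings, n_components = n_components, solver = solver,
                 seed = seed)
  scores <- predict(fit, embeddings)
  rownames(scores) <- rownames(embeddings)
  attr(scores, "extractor") <- fit
  scores
}
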