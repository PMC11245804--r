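# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' All randomness in the pipeline funnels through one master seed; each stage
#' gets its own child so that re-running a stage in isolation reproduces the
#' full run. Kept inside 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param stage character stage name.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 69069 + h * 101) %% 2147483629L) + 1L
}

# sample() that treats a length-1 x as a fixed value, not as 1:x
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# row-normalise a matrix to unit L2 norm; zero rows raise (cosine undefined)
l2_normalise <- function(x, allow_zero = FALSE) {
  nrm <- sqrt(rowSums(x^2))
  if (!allow_zero && any(nrm == 0)) {
    stop("cosine distance undefined for zero vectors", call. = FALSE)
  }
  nrm[nrm == 0] <- 1
  x / nrm
}

# pairwise distances from rows of x to rows of centres, metric in
# c("euclidean", "cosine"); returns n x k matrix
distance_matrix <- function(x, centres, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  x <- as.matrix(x); centres <- as.matrix(centres)
  if (metric == "euclidean") {
    d2 <- outer(rowSums(x^2), rep(1, nrow(centres))) +
      outer(rep(1, nrow(x)), rowSums(centres^2)) - 2 * tcrossprod(x, centres)
    sqrt(pmax(d2, 0))
  } else {
    1 - tcrossprod(l2_normalise(x), l2_normalise(centres))
  }
}

# min-max scaler helpers (fit on training values, clip at transform)
fit_minmax <- function(v) {
  r <- range(v, finite = TRUE)
  if (!all(is.finite(r))) r <- c(0, 1)
  if (diff(r) == 0) r[2] <- r[1] + 1
  list(min = r[1], max = r[2])
}
apply_minmax <- function(v, mm) {
  pmin(pmax((v - mm$min) / (mm$max - mm$min), 0), 1)
}
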