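# PCA extractor shared by the tag and image branches. Two solvers: exact
# ("lapack", eigendecomposition of whichever Gram matrix is smaller) and
# "randomised" (Halko-style range finder with one power iteration), the
# latter being the practical choice for wide image-embedding matrices.

#' Fit a PCA feature extractor
#'
#' @param x numeric matrix, rows = records.
#' @param n_components number of components to keep;
#'   `<= min(nrow(x), ncol(x))`.
#' @param solver `"lapack"` for an exact decomposition or `"randomised"`
#'   for a randomized approximation (oversampling 10, one power iteration).
#' @param seed seed for the randomized solver.
#' @param center center columns before projecting (default `TRUE`).
#' @return an object of class `radclust_pca` with elements `rotation`
#'   (loadings, columns = components), `center`, `sdev` and
#'   `explained_variance_ratio`; project new data with [predict()].
#' @export
fit_pca <- function(x, n_components, solver = c("lapack", "randomised"),
                    seed = 1L, center = TRUE) {
  solver <- match.arg(solver)
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  assert_that(n_components >= 1 && n_components <= min(n, p),
              "n_components must be in [1, min(rows, cols)]")
  ctr <- if (center) colMeans(x) else rep(0, p)
  xc <- sweep(x, 2, ctr)
  total_var <- sum(xc^2) / (n - 1)

  if (solver == "lapack") {
    if (p <= n) {
      e <- eigen(crossprod(xc) / (n - 1), symmetric = TRUE)
      ev <- pmax(e$values, 0)
      rot <- e$vectors[, seq_len(n_components), drop = FALSE]
      sdev <- sqrt(ev[seq_len(n_components)])
    } else {
      e <- eigen(tcrossprod(xc) / (n - 1), symmetric = TRUE)
      ev <- pmax(e$values, 0)
      k <- seq_len(n_components)
      u <- e$vectors[, k, drop = FALSE]
      rot <- crossprod(xc, u)
      rot <- sweep(rot, 2, sqrt(pmax(colSums(rot^2), 1e-300)), "/")
      sdev <- sqrt(ev[k])
    }
  } else {
    set.seed(seed)
    l <- min(p, n_components + 10L)
    omega <- matrix(stats::rnorm(p * l), p, l)
    y <- xc %*% omega
    y <- xc %*% crossprod(xc, y)       # one power iteration
    q <- qr.Q(qr(y))
    b <- crossprod(q, xc)              # l x p
    sv <- svd(b, nu = 0, nv = n_components)
    rot <- sv$v
    sdev <- sv$d[seq_len(n_components)] / sqrt(n - 1)
  }
  dimnames(rot) <- list(colnames(x), paste0("PC", seq_len(n_components)))
  structure(list(rotation = rot, center = ctr, sdev = sdev,
                 explained_variance_ratio = sdev^2 / total_var,
                 solver = solver, n_components = n_components),
            class = "radclust_pca")
}

#' Project data onto fitted principal components
#'
#' @param object a `radclust_pca`.
#' @param newdata numeric matrix with the same columns as the training data.
#' @param ... unused.
#' @return score matrix, `n_components` columns.
#' @export
predict.radclust_pca <- function(object, newdata, ...) {
  sweep(as.matrix(newdata), 2, object$center) %*% object$rotation
}

#' @export
print.radclust_pca <- function(x, ...) {
  cat("<radclust_pca> ", x$n_components, " components (", x$solver,
      " solver), cumulative explained variance ",
      sprintf("%.3f", sum(x$explained_variance_ratio)), "\n", sep = "")
  invisible(x)
}
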