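#' @include fcgrvec-package.R
NULL

# Deterministic SVD sign convention: flip each column of V so its
# largest-magnitude entry is positive (first such entry on exact ties).
.fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

.new_embedding <- function(V, d, f2) {
  structure(list(V = V, singular_values = d, r = ncol(V), f2 = f2,
                 version = 1L),
            class = "fcgr_embedding")
}

#' @export
print.fcgr_embedding <- function(x, ...) {
  cat("FCGR embedding model: f^2 =", x$f2, "-> r =", x$r,
      "; top singular values:",
      paste(signif(utils::head(x$singular_values, 5), 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Fit a rank-r SVD embedding over a feature matrix
#'
#' Computes the truncated singular value decomposition
#' `M ~ U W V^t` and keeps the `r` leading right-singular vectors `V`
#' and singular values. Embedded coordinates are the rows of `M V`
#' (equal to `U W` at full rank, and by construction identical for
#' training rows and projected queries under truncation), which is the
#' form used for kd-tree lookup.
#'
#' @param M numeric `m x f^2` matrix of centered feature vectors
#'   (rows).
#' @param r embedding rank (default 40).
#' @return A list with `model` (class `fcgr_embedding`) and `vectors`
#'   (the `m x r` embedded rows, rownames preserved).
#' @export
fit_svd <- function(M, r = 40L) {
  M <- as.matrix(M)
  r <- as.integer(r)
  if (r <= 0L) stop("r must be positive")
  if (r > min(dim(M))) {
    stop("r (", r, ") exceeds min(dim(M)) = ", min(dim(M)))
  }
  s <- svd(M, nu = 0, nv = r)
  V <- .fix_signs(s$v[, seq_len(r), drop = FALSE])
  model <- .new_embedding(V, s$d[seq_len(r)], ncol(M))
  vectors <- M %*% V
  rownames(vectors) <- rownames(M)
  list(model = model, vectors = vectors)
}

#' Project feature vectors into an embedding
#'
#' Right-multiplies by the model's `V`, the same operation that
#' produced the stored training coordinates, so a training row projects
#' exactly onto its stored embedded row.
#'
#' @param model an `fcgr_embedding`.
#' @param v a length-`f^2` vector or an `n x f^2` matrix.
#' @return A length-`r` vector (or `n x r` matrix).
#' @export
project <- function(model, v) {
  if (is.matrix(v)) {
    if (ncol(v) != model$f2) {
      stop("feature length ", ncol(v), " != model f^2 = ", model$f2)
    }
    return(v %*% model$V)
  }
  if (length(v) != model$f2) {
    stop("feature length ", length(v), " != model f^2 = ", model$f2)
  }
  as.vector(v %*% model$V)
}

#' Fit the embedding on a random row subsample
#'
#' Scalability variant: the SVD is computed on a seeded uniform
#' subsample of the rows and the resulting `V` projects all rows
#' (omitted training rows are handled exactly like query vectors).
#' Deterministic given `seed`.
#'
#' @inheritParams fit_svd
#' @param fraction fraction of rows used for the fit, in `(0, 1]`.
#' @param seed integer seed for the subsample draw.
#' @return As [fit_svd()]; `vectors` covers all `m` rows.
#' @export
fit_svd_subsampled <- function(M, r = 40L, fraction = 0.25, seed = 1L) {
  M <- as.matrix(M)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  m <- nrow(M)
  n_sub <- ceiling(fraction * m)
  if (n_sub < r) {
    stop("subsample of ", n_sub, " rows is smaller than r = ", r)
  }
  idx <- sort(with_seed(seed, sample.int(m, n_sub)))
  fit <- fit_svd(M[idx, , drop = FALSE], r)
  vectors <- M %*% fit$model$V
  rownames(vectors) <- rownames(M)
  list(model = fit$model, vectors = vectors)
}

#' Fit the embedding via the Gram matrix
#'
#' Scalability variant: eigen-decomposes `M^t M` (an `f^2 x f^2`
#' symmetric matrix), whose eigenvectors are the right-singular vectors
#' of `M` and whose eigenvalues are the squared singular values; square
#' roots are taken (negative round-off clamped to zero). The left
#' factor is never formed.
#'
#' @inheritParams fit_svd
#' @return An `fcgr_embedding` (no embedded vectors; use [project()]).
#' @export
fit_svd_gram <- function(M, r = 40L) {
  M <- as.matrix(M)
  r <- as.integer(r)
  if (r <= 0L || r > min(dim(M))) {
    stop("r must be in 1..", min(dim(M)))
  }
  e <- eigen(crossprod(M), symmetric = TRUE)
  d <- sqrt(pmax(e$values[seq_len(r)], 0))
  V <- .fix_signs(e$vectors[, seq_len(r), drop = FALSE])
  .new_embedding(V, d, ncol(M))
}

#' Save / load an embedding archive
#'
#' The archive (a versioned RDS file) stores the model, the embedded
#' corpus and its labels, and the pipeline configuration; reloading
#' reproduces projections bitwise.
#'
#' @param model an `fcgr_embedding`.
#' @param vectors embedded `m x r` matrix.
#' @param labels `data.frame` of per-row ids/labels (or `NULL`).
#' @param config a [pipeline_config()] (or `NULL`).
#' @param path archive file path.
#' @return `path` invisibly (`save_embedding`); the restored list
#'   (`load_embedding`).
#' @export
save_embedding <- function(model, vectors, labels = NULL, config = NULL, path) {
  saveRDS(list(format = "fcgrvec-embedding", version = 1L,
               model = model, vectors = vectors, labels = labels,
               config = config),
          file = path)
  invisible(path)
}

#' @rdname save_embedding
#' @export
load_embedding <- function(path) {
  if (!file.exists(path)) stop("embedding archive not found: ", path)
  x <- readRDS(path)
  if (!identical(x$format, "fcgrvec-embedding")) {
    stop("not an fcgrvec embedding archive: ", path)
  }
  x
}
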