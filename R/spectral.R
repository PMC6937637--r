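#' @include fcgrvec-package.R
NULL

# Orthonormal DCT-IV transform matrix, cached per size.
# C[i, j] = sqrt(2/N) * cos(pi * (i - 1/2) * (j - 1/2) / N), 1-based;
# C is symmetric and involutory (C %*% C = I), so the transform is its
# own inverse.
.dct_iv_matrix <- function(N) {
  key <- paste0("dct", N)
  C <- .fcgrvec_cache[[key]]
  if (is.null(C)) {
    i <- seq_len(N) - 0.5
    C <- sqrt(2 / N) * cos(pi * outer(i, i) / N)
    .fcgrvec_cache[[key]] <- C
  }
  C
}

#' Self-inverting DCT-IV of a vector
#'
#' `X_j = sqrt(2/N) * sum_i x_i cos(pi (i + 1/2)(j + 1/2) / N)`
#' (0-based indices). With this orthonormal scaling the transform is an
#' involution: `dct_iv(dct_iv(x)) == x` to machine precision.
#'
#' @param x numeric vector.
#' @return Numeric vector of the same length.
#' @export
dct_iv <- function(x) {
  N <- length(x)
  if (N < 1L) stop("empty vector")
  as.vector(.dct_iv_matrix(N) %*% x)
}

#' Reduce an FCGR image to its low-frequency DCT-IV block
#'
#' The image is centered by subtracting its global mean (removing the
#' DC component), transformed by the separable 2-D DCT-IV (rows, then
#' columns), and the top-left `f x f` block — the lowest frequencies —
#' is returned.
#'
#' @param image a square numeric matrix (side `2^k`).
#' @param f retained frequencies per dimension (default 30).
#' @return An `f x f` numeric matrix of DCT-IV coefficients.
#' @export
reduce_image <- function(image, f = 30L) {
  N <- nrow(image)
  if (ncol(image) != N) stop("image must be square")
  if (f < 1L || f > N) stop("f must be in 1..", N)
  C <- .dct_iv_matrix(N)
  A <- image - mean(image)
  B <- C %*% A %*% C                 # C symmetric: rows then columns
  B[seq_len(f), seq_len(f), drop = FALSE]
}

#' Flatten a coefficient block to a centered feature vector
#'
#' Row-major flatten (rows appended) followed by subtraction of the
#' vector's own mean, so every feature vector sums to zero.
#'
#' @param block a numeric matrix.
#' @return Numeric vector of length `length(block)` with mean zero.
#' @export
flatten_center <- function(block) {
  v <- as.vector(t(block))
  v - mean(v)
}

#' Full FCGR + DCT feature vector for one sequence
#'
#' Pipeline `fcgr_counts -> fcgr_image -> reduce_image ->
#' flatten_center`: the raw input to the SVD embedding.
#'
#' @param seq nucleotide string.
#' @param k pixelation level (default 7).
#' @param f retained DCT frequencies per dimension (default 30).
#' @return Numeric vector of length `f^2`, mean-centered.
#' @export
seq_features <- function(seq, k = 7L, f = 30L) {
  flatten_center(reduce_image(fcgr_image(fcgr_counts(seq, k)), f))
}

#' Feature matrix for a whole corpus
#'
#' @param corpus a [seq_corpus()].
#' @inheritParams seq_features
#' @return An `m x f^2` numeric matrix with row names from `corpus$id`.
#' @export
corpus_features <- function(corpus, k = 7L, f = 30L) {
  M <- t(vapply(corpus$sequence, seq_features, numeric(f * f), k = k, f = f,
                USE.NAMES = FALSE))
  rownames(M) <- corpus$id
  M
}
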