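#' @include fcgrvec-package.R
NULL

# Chaos-game corner convention (Jeffrey): in the unit square
#   A = (0,0), T = (1,0), C = (0,1), G = (1,1)
# so purines (A, G) sit diagonally opposite, as do pyrimidines (C, T).
# Matrix row 1 is the TOP of the square (y near 1). Per-base bits:
#   x bit 1 for G/T (right half), y bit 1 for C/G (top half).
.BASE_X <- c(A = 0L, C = 0L, G = 1L, T = 1L)
.BASE_Y <- c(A = 0L, C = 1L, G = 1L, T = 0L)

#' Map a k-mer to its FCGR pixel
#'
#' Under the corner convention A = (0,0), C = (0,1), G = (1,1),
#' T = (1,0), the chaos-game midpoint iteration started at (0.5, 0.5)
#' lands, after consuming the k-mer, in the returned pixel of the
#' `2^k x 2^k` grid. The mapping is a bijection between k-mers and
#' pixels; it is computed bitwise, with the last nucleotide contributing
#' the most significant coordinate bit.
#'
#' @param kmer a string over A/C/G/T.
#' @return Integer `c(row, col)`, 1-based, row 1 at the top of the
#'   square.
#' @export
kmer_to_pixel <- function(kmer) {
  k <- nchar(kmer)
  if (k < 1L) stop("kmer must be nonempty")
  ch <- strsplit(toupper(kmer), "", fixed = TRUE)[[1]]
  if (any(!ch %in% names(.BASE_X))) {
    stop("invalid character in kmer: ", paste(setdiff(ch, names(.BASE_X)), collapse = ", "))
  }
  w <- 2^(seq_len(k) - 1)             # position j gets weight 2^(j-1)
  col0 <- sum(.BASE_X[ch] * w)
  y0 <- sum(.BASE_Y[ch] * w)
  row0 <- 2^k - 1 - y0                # row 1 = top
  c(row = as.integer(row0) + 1L, col = as.integer(col0) + 1L)
}

#' Tally a sequence's k-mers into an FCGR count matrix
#'
#' Every sliding window of length `k` made only of A/C/G/T increments
#' the count of its pixel (see [kmer_to_pixel()]); windows containing
#' any other IUPAC code are skipped entirely, and the skipped fraction
#' is recorded in attribute `skipped`.
#'
#' @param seq a nucleotide string (case-insensitive).
#' @param k pixelation level (1-12, default 7); the matrix is
#'   `2^k x 2^k`.
#' @return Integer count matrix with attributes `k` and `skipped`.
#' @export
fcgr_counts <- function(seq, k = 7L) {
  k <- as.integer(k)
  if (k < 1L || k > 12L) stop("k must be in 1..12")
  s <- toupper(seq)
  L <- nchar(s)
  if (L < k) stop("sequence shorter than k (", L, " < ", k, ")")
  code <- utf8ToInt(s)
  xb <- integer(L); yb <- integer(L); bad <- rep(TRUE, L)
  is <- function(letter) code == utf8ToInt(letter)
  a <- is("A"); c_ <- is("C"); g <- is("G"); t_ <- is("T")
  xb[g | t_] <- 1L
  yb[c_ | g] <- 1L
  bad[a | c_ | g | t_] <- FALSE
  nwin <- L - k + 1L
  col0 <- numeric(nwin); y0 <- numeric(nwin); nbad <- integer(nwin)
  for (j in seq_len(k)) {
    sel <- j:(nwin + j - 1L)
    wgt <- 2^(j - 1)
    col0 <- col0 + xb[sel] * wgt
    y0 <- y0 + yb[sel] * wgt
    nbad <- nbad + bad[sel]
  }
  side <- 2L^k
  ok <- nbad == 0L
  row0 <- side - 1 - y0
  idx <- row0[ok] * side + col0[ok] + 1   # row-major pixel index
  counts <- matrix(tabulate(idx, nbins = side * side),
                   nrow = side, ncol = side, byrow = TRUE)
  storage.mode(counts) <- "integer"
  attr(counts, "k") <- k
  attr(counts, "skipped") <- (nwin - sum(ok)) / nwin
  counts
}

#' Rescale FCGR counts to a displayable image
#'
#' Counts are normalized so the maximum is one, then the (real) fifth
#' root is taken elementwise, which keeps sparse high-k images from
#' rendering almost entirely dark. An all-zero count matrix maps to an
#' all-zero image.
#'
#' @param counts a non-negative count matrix (from [fcgr_counts()]).
#' @return A numeric matrix in `[0, 1]` of the same shape.
#' @export
fcgr_image <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  m <- max(counts)
  img <- if (m == 0) matrix(0, nrow(counts), ncol(counts)) else (counts / m)^(1 / 5)
  attr(img, "k") <- attr(counts, "k")
  img
}

#' Compute a genome's FCGR image
#'
#' Convenience wrapper running [fcgr_counts()] then [fcgr_image()].
#'
#' @inheritParams fcgr_counts
#' @return An object of class `fcgr`: list with elements `k`, `counts`,
#'   `image`, `skipped`.
#' @export
fcgr <- function(seq, k = 7L) {
  counts <- fcgr_counts(seq, k)
  structure(
    list(k = attr(counts, "k"), counts = counts,
         image = fcgr_image(counts), skipped = attr(counts, "skipped")),
    class = "fcgr"
  )
}

#' @export
print.fcgr <- function(x, ...) {
  cat("FCGR image: k =", x$k, "(", nrow(x$counts), "x", ncol(x$counts),
      "), total k-mer count", sum(x$counts),
      sprintf(", %.2f%% windows skipped\n", 100 * x$skipped))
  invisible(x)
}

#' Export an FCGR image as a grayscale PNG
#'
#' Presentation-only helper (requires the `png` package); pixel
#' intensity is the rescaled k-mer frequency.
#'
#' @param x an `fcgr` object or image matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_fcgr_png <- function(x, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("PNG export needs the 'png' package")
  }
  img <- if (inherits(x, "fcgr")) x$image else x
  png::writePNG(img, target = path)
  invisible(path)
}
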