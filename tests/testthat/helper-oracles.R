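# Independent oracles used to verify the package's fast paths.

# Chaos-game midpoint iteration, run numerically and binned at 2^k.
# Corner convention: A=(0,0), C=(0,1), G=(1,1), T=(1,0); row 1 = top.
cgr_pixel_oracle <- function(kmer, k = nchar(kmer)) {
  corners <- list(A = c(0, 0), C = c(0, 1), G = c(1, 1), T = c(1, 0))
  p <- c(0.5, 0.5)
  for (ch in strsplit(kmer, "", fixed = TRUE)[[1]]) {
    p <- (p + corners[[ch]]) / 2
  }
  side <- 2^k
  c(row = side - floor(p[2] * side), col = floor(p[1] * side) + 1)
}

# Dictionary-based k-mer counter: substring extraction + table(),
# pixels placed by the midpoint iteration above.
fcgr_counts_oracle <- function(seq, k) {
  s <- toupper(seq)
  L <- nchar(s)
  w <- substring(s, 1:(L - k + 1), k:L)
  w <- w[grepl("^[ACGT]+$", w)]
  side <- 2^k
  counts <- matrix(0L, side, side)
  if (length(w)) {
    tab <- table(w)
    for (i in seq_along(tab)) {
      px <- cgr_pixel_oracle(names(tab)[i], k)
      counts[px[1], px[2]] <- counts[px[1], px[2]] + as.integer(tab[i])
    }
  }
  counts
}

# DCT-IV straight from the definition sum.
dct_iv_oracle <- function(x) {
  N <- length(x)
  i <- seq_len(N) - 0.5
  vapply(i, function(j) sqrt(2 / N) * sum(x * cos(pi * i * j / N)), numeric(1))
}

# Naive direct-sum 2-D DCT-IV of the centered image, top-left f x f.
reduce_image_oracle <- function(image, f) {
  N <- nrow(image)
  A <- image - mean(image)
  i <- seq_len(N) - 0.5
  cosN <- function(j) cos(pi * i * j / N)
  out <- matrix(0, f, f)
  for (j1 in seq_len(f)) {
    for (j2 in seq_len(f)) {
      out[j1, j2] <- (2 / N) * sum(outer(cosN(j1 - 0.5), cosN(j2 - 0.5)) * A)
    }
  }
  out
}

# Brute-force K-nearest-neighbor scan, ties by insertion order.
brute_knn <- function(X, q, K) {
  d2 <- colSums((t(X) - q)^2)
  ord <- order(d2, seq_len(nrow(X)))[seq_len(K)]
  list(idx = ord, dist = sqrt(d2[ord]))
}

# Robinson-Foulds by explicit bipartition enumeration.
tree_splits_oracle <- function(ph) {
  ph <- ape::unroot(ph)
  n <- length(ph$tip.label)
  tips <- sort(ph$tip.label)
  splits <- character(0)
  internal <- unique(ph$edge[, 2][ph$edge[, 2] > n])
  for (node in internal) {
    side <- sort(ape::extract.clade(ph, node)$tip.label)
    other <- setdiff(tips, side)
    if (length(side) < 2 || length(other) < 2) next
    a <- paste(side, collapse = "|")
    b <- paste(sort(other), collapse = "|")
    splits <- c(splits, if (a < b) a else b)
  }
  unique(splits)
}

rf_oracle <- function(p1, p2) {
  s1 <- tree_splits_oracle(p1)
  s2 <- tree_splits_oracle(p2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# random ACGT (optionally with ambiguity codes mixed in)
random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
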