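#' @include fcgrvec-package.R
NULL

#' Pairwise distance matrix over embedded vectors
#'
#' Cosine distance (`1 - u.v / (|u||v|)`, range `[0, 2]`) is the
#' default for tree building; Euclidean and Manhattan are also
#' available.
#'
#' @param vectors `n x r` numeric matrix with row names as labels.
#' @param metric one of `"cosine"`, `"euclidean"`, `"manhattan"`.
#' @return A symmetric `n x n` matrix with zero diagonal, dimnames from
#'   the row names, and attribute `metric`.
#' @export
distance_matrix <- function(vectors,
                            metric = c("cosine", "euclidean", "manhattan")) {
  metric <- match.arg(metric)
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < 2L) stop("need at least two vectors")
  labels <- rownames(vectors) %||% as.character(seq_len(n))
  D <- switch(metric,
    cosine = {
      nrm <- sqrt(rowSums(vectors^2))
      if (any(nrm == 0)) {
        stop("zero vector(s) under cosine distance: ",
             paste(labels[nrm == 0], collapse = ", "))
      }
      Vn <- vectors / nrm
      M <- 1 - tcrossprod(Vn)
      pmin(pmax(M, 0), 2)
    },
    euclidean = as.matrix(stats::dist(vectors, method = "euclidean")),
    manhattan = as.matrix(stats::dist(vectors, method = "manhattan"))
  )
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(labels, labels)
  attr(D, "metric") <- metric
  D
}

#' Agglomerative tree from a distance matrix
#'
#' Standard hierarchical clustering (default average linkage) over the
#' embedded-vector distances; leaves carry sequence ids and internal
#' nodes carry merge heights.
#'
#' @param D a [distance_matrix()] (or any symmetric distance matrix
#'   with dimnames).
#' @param linkage `"average"` (default), `"complete"`, `"single"`, or
#'   `"ward"`.
#' @return An `hclust` object (convert with [tree_newick()] /
#'   [as_phylo_tree()]).
#' @export
build_tree <- function(D, linkage = c("average", "complete", "single", "ward")) {
  linkage <- match.arg(linkage)
  if (nrow(D) < 2L) stop("need at least two leaves")
  method <- if (linkage == "ward") "ward.D2" else linkage
  stats::hclust(stats::as.dist(D), method = method)
}

#' Convert a merge tree to ape's phylo representation
#'
#' Branch lengths are parent height minus child height (leaves sit at
#' height zero).
#'
#' @param tree an `hclust` (or already a `phylo`).
#' @return An [ape::as.phylo()] tree.
#' @export
as_phylo_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  ape::as.phylo(tree)
}

#' Write / read a tree as Newick
#'
#' @param tree an `hclust` or `phylo` tree.
#' @param path optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (`tree_newick`) or a `phylo`
#'   (`read_newick`).
#' @export
tree_newick <- function(tree, path = NULL) {
  ph <- as_phylo_tree(tree)
  if (is.null(path)) ape::write.tree(ph) else {
    ape::write.tree(ph, file = path)
    invisible(path)
  }
}

#' @rdname tree_newick
#' @export
read_newick <- function(path) {
  if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix and embeds on the top
#' eigenpairs; negative eigenvalues are truncated to zero (their axes
#' contribute nothing). Output coordinates are centered at the origin
#' with each axis's sign fixed so its largest-magnitude coordinate is
#' positive. Euclidean-embeddable inputs are reproduced exactly.
#'
#' @param D a distance matrix (object of [distance_matrix()] form).
#' @param dims 2 or 3 output dimensions.
#' @return `n x dims` coordinate matrix with attributes `eig`
#'   (eigenvalues, non-increasing) and `variance_fraction`.
#' @export
classical_mds <- function(D, dims = 2L) {
  dims <- as.integer(dims)
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3")
  n <- nrow(D)
  if (n <= dims) stop("need more than ", dims, " points for ", dims, "-D MDS")
  B <- -0.5 * scale(t(scale(t(as.matrix(D)^2), center = TRUE, scale = FALSE)),
                    center = TRUE, scale = FALSE)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  lam <- pmax(e$values[seq_len(dims)], 0)
  # eigenvalues at round-off scale are degenerate axes, not signal
  lam[lam <= max(abs(e$values)) * 1e-12] <- 0
  X <- e$vectors[, seq_len(dims), drop = FALSE] %*% diag(sqrt(lam), dims)
  X <- .fix_signs(X)
  X <- sweep(X, 2, colMeans(X))
  rownames(X) <- rownames(D)
  attr(X, "eig") <- e$values
  attr(X, "variance_fraction") <-
    sum(lam) / sum(pmax(e$values, 0))
  X
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of the non-trivial bipartitions of the
#' two trees, both read unrooted; leaf sets must match.
#'
#' @param t1,t2 trees (`hclust`, `phylo`, Newick strings, or Newick
#'   file paths).
#' @return Integer RF distance.
#' @export
robinson_foulds <- function(t1, t2) {
  as_tree <- function(x) {
    if (inherits(x, "phylo")) x
    else if (inherits(x, "hclust")) as_phylo_tree(x)
    else if (is.character(x) && length(x) == 1L) read_newick(x)
    else stop("cannot interpret tree input")
  }
  p1 <- as_tree(t1); p2 <- as_tree(t2)
  d <- setdiff(p1$tip.label, p2$tip.label)
  d2 <- setdiff(p2$tip.label, p1$tip.label)
  if (length(d) || length(d2)) {
    stop("leaf sets differ; only in tree 1: {",
         paste(d, collapse = ", "), "}; only in tree 2: {",
         paste(d2, collapse = ", "), "}")
  }
  as.integer(phangorn::RF.dist(ape::unroot(p1), ape::unroot(p2),
                               check.labels = TRUE))
}
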