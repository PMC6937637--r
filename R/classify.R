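#' @include fcgrvec-package.R
NULL

#' Build an exact nearest-neighbor reference index
#'
#' Stores embedded training vectors and their labels in a kd-tree
#' supporting exact Euclidean nearest-neighbor queries. Any stored
#' vector retrieves itself at (numerically) zero distance; ties in
#' distance are broken by insertion order.
#'
#' @param vectors `m x r` numeric matrix of embedded vectors.
#' @param labels `data.frame` with one row per vector; any taxonomy
#'   rank columns (`order`, `family`, `genus`, `species`, `strain`) are
#'   used by the classifiers.
#' @param ids character ids (default: `labels$id`, else rownames of
#'   `vectors`).
#' @return An object of class `ref_index`.
#' @export
build_index <- function(vectors, labels = NULL, ids = NULL) {
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (is.null(ids)) {
    ids <- if (!is.null(labels) && "id" %in% names(labels)) labels$id
           else rownames(vectors) %||% as.character(seq_len(nrow(vectors)))
  }
  if (length(ids) != nrow(vectors)) stop("one id per vector required")
  if (is.null(labels)) {
    labels <- data.frame(id = ids, stringsAsFactors = FALSE)
  }
  if (nrow(labels) != nrow(vectors)) stop("one label row per vector required")
  obj <- new.env(parent = emptyenv())
  obj$vectors <- vectors
  obj$ids <- as.character(ids)
  obj$labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  obj$ptr <- .kd_build(vectors)
  structure(obj, class = "ref_index")
}

#' @export
print.ref_index <- function(x, ...) {
  cat("Reference index:", nrow(x$vectors), "vectors of dimension",
      ncol(x$vectors), "\n")
  invisible(x)
}

# external pointers do not survive serialization; rebuild on demand
.index_ptr <- function(index) {
  if (!.kd_valid(index$ptr)) index$ptr <- .kd_build(index$vectors)
  index$ptr
}

.as_query_matrix <- function(index, q) {
  if (!is.matrix(q)) q <- matrix(q, nrow = 1)
  storage.mode(q) <- "double"
  if (ncol(q) != ncol(index$vectors)) {
    stop("query dimension ", ncol(q), " != index dimension ",
         ncol(index$vectors))
  }
  q
}

.rank_labels <- function(index, rank) {
  if (!rank %in% names(index$labels)) {
    stop("rank '", rank, "' not present in the training labels")
  }
  index$labels[[rank]]
}

#' K nearest neighbors of a query vector
#'
#' Exact Euclidean K-nearest-neighbor lookup in the kd-tree; identical
#' to a brute-force scan, with distance ties broken by insertion order.
#'
#' @param index a [build_index()] reference index.
#' @param q a length-`r` query vector (or one-row matrix).
#' @param K number of neighbors (clamped to the index size with a
#'   warning).
#' @return A `data.frame` of the K neighbors in order: `id`,
#'   `distance`, plus the index's label columns.
#' @export
nearest_neighbors <- function(index, q, K = 1L) {
  if (K < 1L) stop("K must be >= 1")
  m <- nrow(index$vectors)
  if (K > m) {
    warning("K = ", K, " exceeds index size ", m, "; clamped")
    K <- m
  }
  res <- .kd_query(.index_ptr(index), .as_query_matrix(index, q), as.integer(K))
  i <- res$idx[1, ]
  out <- data.frame(id = index$ids[i], distance = res$dist[1, ],
                    stringsAsFactors = FALSE)
  lab <- index$labels[i, setdiff(names(index$labels), "id"), drop = FALSE]
  rownames(lab) <- NULL
  cbind(out, lab)
}

# batch top-1 lookup: returns list(idx, dist) over query rows
.nn1_batch <- function(index, Q) {
  res <- .kd_query(.index_ptr(index), .as_query_matrix(index, Q), 1L)
  list(idx = res$idx[, 1], dist = res$dist[, 1])
}

#' Classify a query by its single nearest neighbor
#'
#' @inheritParams nearest_neighbors
#' @param rank taxonomy rank to read off the winning neighbor
#'   (default `"species"`).
#' @return The neighbor's label at `rank` (character scalar).
#' @export
classify_nn <- function(index, q, rank = "species") {
  labs <- .rank_labels(index, rank)
  nn <- .nn1_batch(index, .as_query_matrix(index, q))
  lab <- labs[nn$idx[1]]
  if (is.na(lab)) {
    stop("nearest neighbor '", index$ids[nn$idx[1]], "' has no '", rank,
         "' label")
  }
  lab
}

#' Candidate label pool from the top-K neighbors
#'
#' Distinct labels of the K nearest neighbors in first-appearance
#' order; the top-1 label always comes first.
#'
#' @inheritParams classify_nn
#' @param K pool depth (default 20).
#' @return Character vector of distinct candidate labels.
#' @export
candidate_pool <- function(index, q, K = 20L, rank = "species") {
  nn <- nearest_neighbors(index, q, K)
  labs <- nn[[rank]]
  unique(labs[!is.na(labs)])
}

#' Majority-vote classification of a multi-chunk genome
#'
#' Each chunk vector votes with its nearest neighbor's label; the most
#' frequent label wins. Ties go to the tied label with the smallest
#' best neighbor distance, then lexicographically.
#'
#' @param index a [build_index()] reference index.
#' @param queries `n_chunks x r` matrix of the genome's chunk vectors.
#' @param rank taxonomy rank (default `"species"`).
#' @return The winning label (character scalar).
#' @export
majority_classify <- function(index, queries, rank = "species") {
  Q <- .as_query_matrix(index, queries)
  if (nrow(Q) < 1L) stop("at least one query vector required")
  labs <- .rank_labels(index, rank)
  nn <- .nn1_batch(index, Q)
  votes <- labs[nn$idx]
  if (anyNA(votes)) {
    stop("nearest neighbor '", index$ids[nn$idx[which(is.na(votes))[1]]],
         "' has no '", rank, "' label")
  }
  tab <- table(votes)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L) {
    best <- vapply(top, function(lb) min(nn$dist[votes == lb]), numeric(1))
    top <- top[order(best, top)]
  }
  top[1]
}

#' Consensus host genera for a viral query
#'
#' Finds the `n_neighbors` nearest reference (bacterial chunk) vectors
#' and keeps every label at `rank` occurring at least `min_count`
#' times, ordered by count, then by that label's best distance. The
#' defaults (28 neighbors, two-or-more consensus) give close to three
#' genus guesses per phage on the corpora the method was developed on.
#'
#' @inheritParams classify_nn
#' @param n_neighbors neighbors retrieved (default 28).
#' @param min_count minimum occurrences for a label to be retained
#'   (default 2).
#' @return Character vector of consensus labels (possibly empty).
#' @export
consensus_hosts <- function(index, q, n_neighbors = 28L, min_count = 2L,
                            rank = "genus") {
  if (min_count < 1L || n_neighbors < min_count) {
    stop("need n_neighbors >= min_count >= 1")
  }
  nn <- nearest_neighbors(index, q, n_neighbors)
  labs <- nn[[rank]]
  keep <- !is.na(labs)
  labs <- labs[keep]; dists <- nn$distance[keep]
  if (length(labs) == 0L) return(character(0))
  tab <- table(labs)
  cand <- names(tab)[tab >= min_count]
  if (length(cand) == 0L) return(character(0))
  best <- vapply(cand, function(lb) min(dists[labs == lb]), numeric(1))
  cand[order(-as.integer(tab[cand]), best, cand)]
}

#' Calibrate the host-prediction neighbor count
#'
#' Sweeps `n_neighbors` over `range` and returns the value whose mean
#' consensus-set size over the queries is closest to
#' `target_avg_guesses` (ties favor the smaller count). The mean set
#' size is non-decreasing in the neighbor count.
#'
#' @param index a [build_index()] reference index.
#' @param queries `n x r` matrix of query vectors.
#' @param min_count consensus threshold (default 2).
#' @param target_avg_guesses desired mean set size (default 3).
#' @param range candidate neighbor counts (default `2:60`).
#' @param rank taxonomy rank (default `"genus"`).
#' @return The calibrated neighbor count (integer), with the achieved
#'   mean set size in attribute `mean_guesses`.
#' @export
calibrate_neighbor_count <- function(index, queries, min_count = 2L,
                                     target_avg_guesses = 3,
                                     range = 2:60, rank = "genus") {
  Q <- .as_query_matrix(index, queries)
  range <- sort(unique(as.integer(range)))
  range <- range[range >= min_count & range <= nrow(index$vectors)]
  if (length(range) == 0L) stop("empty calibration range")
  means <- vapply(range, function(nn) {
    sizes <- vapply(seq_len(nrow(Q)), function(i) {
      length(consensus_hosts(index, Q[i, ], n_neighbors = nn,
                             min_count = min_count, rank = rank))
    }, numeric(1))
    mean(sizes)
  }, numeric(1))
  best <- which.min(abs(means - target_avg_guesses))  # first = smallest n
  structure(range[best], mean_guesses = means[best])
}

#' Score predictions against the truth
#'
#' @param predictions `data.frame` with columns `query_id`, `predicted`
#'   (top-1 label), and optionally `candidates` and `consensus`
#'   (semicolon-joined label lists).
#' @param truth `data.frame` with columns `id` and the rank column, or
#'   a named character vector of true labels.
#' @param rank taxonomy rank being scored.
#' @return One-row `data.frame`: `n`, `top1_pct`, `pool_pct`,
#'   `consensus_pct` (percentages over queries with truth at the rank;
#'   `NA` for columns absent from `predictions`).
#' @export
evaluate <- function(predictions, truth, rank = "species") {
  tr <- if (is.data.frame(truth)) {
    stats::setNames(truth[[rank]], truth$id)
  } else truth
  y <- tr[predictions$query_id]
  ok <- !is.na(y)
  y <- y[ok]; pred <- predictions[ok, , drop = FALSE]
  n <- length(y)
  if (n == 0L) stop("no queries with truth at rank '", rank, "'")
  in_list <- function(col) {
    if (!col %in% names(pred)) return(NA_real_)
    hits <- mapply(function(s, t) t %in% strsplit(s, ";", fixed = TRUE)[[1]],
                   pred[[col]], y)
    100 * mean(hits)
  }
  data.frame(n = n,
             top1_pct = 100 * mean(pred$predicted == y),
             pool_pct = in_list("candidates"),
             consensus_pct = in_list("consensus"))
}

#' Write an evaluation or prediction table as TSV
#'
#' @param x a `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
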