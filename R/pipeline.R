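#' @include fcgrvec-package.R
NULL

#' Pipeline configuration
#'
#' Bundles every tunable of the sequence-to-vector pipeline with the
#' defaults the method was developed at: pixelation level `k = 7`
#' (128 x 128 FCGR images), `f = 30` retained DCT-IV frequencies per
#' dimension, embedding rank `r = 40` (80 is reserved for
#' classifier-training variants), 20 kb chunks with at most 37 per
#' genome, Euclidean lookup with a top-20 candidate pool, cosine
#' distance with average linkage for trees, and 28 host neighbors with
#' two-or-more consensus.
#'
#' @param k pixelation level.
#' @param f retained DCT frequencies per dimension.
#' @param r embedding rank.
#' @param chunk_len chunk length (bp).
#' @param max_chunks maximum chunks per genome.
#' @param lookup_metric metric for nearest-neighbor lookup.
#' @param tree_metric metric for tree distance matrices.
#' @param linkage agglomeration linkage.
#' @param K_pool candidate-pool depth.
#' @param n_neighbors host-prediction neighbor count.
#' @param min_count host-prediction consensus threshold.
#' @param seed integer seed for all randomized steps.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 7L, f = 30L, r = 40L, chunk_len = 20000L,
                            max_chunks = 37L, lookup_metric = "euclidean",
                            tree_metric = "cosine", linkage = "average",
                            K_pool = 20L, n_neighbors = 28L, min_count = 2L,
                            seed = 1L) {
  cfg <- list(k = as.integer(k), f = as.integer(f), r = as.integer(r),
              chunk_len = as.integer(chunk_len),
              max_chunks = as.integer(max_chunks),
              lookup_metric = lookup_metric, tree_metric = tree_metric,
              linkage = linkage, K_pool = as.integer(K_pool),
              n_neighbors = as.integer(n_neighbors),
              min_count = as.integer(min_count), seed = as.integer(seed))
  stopifnot(cfg$k >= 1, cfg$k <= 12, cfg$f >= 1, cfg$f <= 2^cfg$k,
            cfg$r >= 1, cfg$chunk_len >= 1, cfg$max_chunks >= 1,
            cfg$K_pool >= 1, cfg$n_neighbors >= cfg$min_count,
            cfg$min_count >= 1)
  stopifnot(cfg$lookup_metric %in% c("euclidean", "cosine", "manhattan"),
            cfg$tree_metric %in% c("cosine", "euclidean", "manhattan"),
            cfg$linkage %in% c("average", "complete", "single", "ward"))
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("fcgrvec pipeline config:\n")
  for (nm in names(x)) cat(" ", nm, "=", as.character(x[[nm]]), "\n")
  invisible(x)
}

#' Write / read a pipeline configuration file
#'
#' Plain `key: value` YAML.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `path` invisibly (`write_config`); a [pipeline_config()]
#'   (`read_config`).
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(nm) {
    paste0(nm, ": ", as.character(config[[nm]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, ":\\s*")
  vals <- stats::setNames(lapply(kv, function(p) trimws(p[2])),
                          vapply(kv, `[[`, character(1), 1))
  do.call(pipeline_config, vals)
}

#' Embed a corpus end to end
#'
#' Runs FCGR, DCT reduction and SVD embedding over an already-chunked
#' (or whole-genome) corpus and builds the lookup index.
#'
#' @param corpus a [seq_corpus()].
#' @param config a [pipeline_config()].
#' @param subsample_fraction optional row fraction for the subsampled
#'   SVD variant (`NULL` = full fit).
#' @return A list: `model`, `vectors`, `index`, `features`.
#' @export
embed_corpus <- function(corpus, config = pipeline_config(),
                         subsample_fraction = NULL) {
  M <- corpus_features(corpus, k = config$k, f = config$f)
  if (config$r > min(dim(M))) {
    stop("r = ", config$r, " exceeds min(m, f^2) = ", min(dim(M)),
         "; reduce r or supply more sequences")
  }
  fit <- if (is.null(subsample_fraction)) {
    fit_svd(M, config$r)
  } else {
    fit_svd_subsampled(M, config$r, fraction = subsample_fraction,
                       seed = config$seed)
  }
  labels <- corpus[, intersect(c("id", "parent", .RANKS), names(corpus)),
                   drop = FALSE]
  index <- build_index(fit$vectors, labels = labels, ids = corpus$id)
  list(model = fit$model, vectors = fit$vectors, index = index, features = M)
}
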