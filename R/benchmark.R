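#' @include fcgrvec-package.R
NULL

#' Randomized species-recovery trials over a feature matrix
#'
#' Runs the repeated randomized-split recognition protocol: in each
#' trial the genomes are split 75/25 stratified by species, an SVD
#' embedding of rank `r` is fitted on the training rows, held-out rows
#' are classified by their nearest training neighbor, and per-genome
#' labels are derived by majority vote over each genome's rows. When
#' every row is its own genome the two accuracies coincide.
#'
#' @param features `m x f^2` feature matrix ([corpus_features()]).
#' @param species character species label per row.
#' @param genome genome id per row (default: each row is one genome);
#'   the train/test split is drawn at genome level so chunks of one
#'   genome never straddle the split.
#' @param n_trials number of randomized trials (default 20).
#' @param seed integer seed; trial `t` uses `seed + t`.
#' @param r embedding rank (default 40).
#' @param subsample_fraction optional fraction for the subsampled-SVD
#'   variant.
#' @param train_fraction training fraction (default 0.75, rounded
#'   down).
#' @return A `data.frame` with one row per trial: `trial`,
#'   `chunk_accuracy` (per-row top-1), `genome_accuracy` (per-genome
#'   majority).
#' @export
run_recovery_trials <- function(features, species, genome = NULL,
                                n_trials = 20L, seed = 1L, r = 40L,
                                subsample_fraction = NULL,
                                train_fraction = 0.75) {
  features <- as.matrix(features)
  m <- nrow(features)
  if (length(species) != m) stop("one species label per row required")
  if (is.null(genome)) genome <- rownames(features) %||% as.character(seq_len(m))
  genomes <- unique(genome)
  g_species <- species[match(genomes, genome)]
  res <- lapply(seq_len(n_trials), function(t) {
    tseed <- seed + t
    g_train <- logical(length(genomes))
    with_seed(tseed, {
      for (sp in unique(g_species)) {
        i <- which(g_species == sp)
        g_train[sample(i, floor(train_fraction * length(i)))] <- TRUE
      }
    })
    tr <- genome %in% genomes[g_train]
    if (sum(tr) < r) {
      stop("training split of ", sum(tr), " rows cannot support rank ", r)
    }
    fit <- if (is.null(subsample_fraction)) {
      fit_svd(features[tr, , drop = FALSE], r)
    } else {
      fit_svd_subsampled(features[tr, , drop = FALSE], r,
                         fraction = subsample_fraction, seed = tseed)
    }
    index <- build_index(fit$vectors,
                         labels = data.frame(id = which(tr),
                                             species = species[tr]))
    qvec <- project(fit$model, features[!tr, , drop = FALSE])
    pred <- vapply(seq_len(nrow(qvec)), function(i) {
      classify_nn(index, qvec[i, ], rank = "species")
    }, character(1))
    truth <- species[!tr]
    test_genomes <- genome[!tr]
    g_pred <- vapply(unique(test_genomes), function(gid) {
      majority_classify(index, qvec[test_genomes == gid, , drop = FALSE],
                        rank = "species")
    }, character(1))
    g_truth <- species[!tr][match(unique(test_genomes), test_genomes)]
    data.frame(trial = t,
               chunk_accuracy = mean(pred == truth),
               genome_accuracy = mean(g_pred == g_truth))
  })
  do.call(rbind, res)
}
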