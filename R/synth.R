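#' @include fcgrvec-package.R
NULL

.BASES <- c("A", "C", "G", "T")

#' Generate species-specific Markov sequence models
#'
#' Each "species" is an order-`order` Markov transition model over
#' {A,C,G,T} whose rows are drawn from a symmetric Dirichlet with the
#' given `concentration` (lower concentration gives more distinct
#' species and an easier classification problem; the limit of large
#' concentration is a uniform i.i.d. model). Species are grouped in
#' pairs into "genera" so genus-level protocols are exercisable.
#'
#' @param n_species number of species models.
#' @param order Markov order (default 2; contexts are the last `order`
#'   bases, oldest base most significant in the row index).
#' @param concentration Dirichlet concentration parameter (default 1).
#' @param seed integer seed; the same seed reproduces the same models.
#' @return A list of `species_model` objects with fields `name`,
#'   `genus`, `order`, `transition` (a `4^order x 4` row-stochastic
#'   matrix).
#' @export
make_species <- function(n_species, order = 2L, concentration = 1,
                         seed = 1L) {
  stopifnot(n_species >= 1, order >= 0, concentration > 0)
  nctx <- 4L^order
  with_seed(seed, {
    lapply(seq_len(n_species), function(i) {
      g <- matrix(stats::rgamma(nctx * 4L, shape = concentration),
                  nrow = nctx, ncol = 4L)
      structure(
        list(name = sprintf("sp%02d", i),
             genus = sprintf("gen%s", LETTERS[(i - 1L) %/% 2L + 1L]),
             order = as.integer(order),
             transition = g / rowSums(g)),
        class = "species_model"
      )
    })
  })
}

#' @export
print.species_model <- function(x, ...) {
  cat("Species model", x$name, "(genus", paste0(x$genus, ")"),
      "- Markov order", x$order, "\n")
  invisible(x)
}

#' Sample one genome from a species model
#'
#' Sequences are drawn hierarchically: the species transition table is
#' first perturbed per genome (rows redrawn from a Dirichlet centered
#' on the species rows with concentration `genome_kappa`), modeling the
#' strain-level k-mer signature that makes fragments of one genome
#' resemble each other more than fragments of other genomes of the same
#' species; i.i.d. substitutions at `mutation_rate` are then applied.
#' Deterministic per seed.
#'
#' @param model a `species_model`.
#' @param length genome length in bp.
#' @param mutation_rate i.i.d. substitution probability per base
#'   (default 0.02).
#' @param seed integer seed.
#' @param genome_kappa Dirichlet concentration of the per-genome
#'   transition perturbation (default 200, a few percent jitter;
#'   `Inf` disables it).
#' @param id sequence id (default derived from species name and seed).
#' @return A one-row [seq_corpus()] with `species` and `genus` labels.
#' @export
sample_genome <- function(model, length, mutation_rate = 0.02, seed = 1L,
                          genome_kappa = 200, id = NULL) {
  stopifnot(length >= model$order + 1L, mutation_rate >= 0, mutation_rate < 1)
  codes <- with_seed(seed, {
    tr <- model$transition
    if (is.finite(genome_kappa)) {
      g <- matrix(stats::rgamma(base::length(tr), shape = genome_kappa * tr),
                  nrow = nrow(tr))
      tr <- g / rowSums(g)
    }
    x <- .markov_sample(tr, model$order, as.integer(length))
    if (mutation_rate > 0) {
      hit <- which(stats::runif(length) < mutation_rate)
      if (base::length(hit) > 0L) {
        # substitute with one of the three other bases, uniformly
        x[hit] <- (x[hit] + sample(1:3, base::length(hit), replace = TRUE)) %% 4L
      }
    }
    x
  })
  seq <- paste(.BASES[codes + 1L], collapse = "")
  seq_corpus(id %||% sprintf("%s_g%d", model$name, seed), seq,
             labels = data.frame(species = model$name, genus = model$genus,
                                 stringsAsFactors = FALSE))
}

#' Stationary base distribution of a species model
#'
#' Solves for the stationary distribution of the context chain and
#' marginalizes to the next-base distribution; used to sanity-check
#' sampled base compositions.
#'
#' @param model a `species_model`.
#' @return Length-4 probability vector (A, C, G, T).
#' @export
stationary_base_distribution <- function(model) {
  tr <- model$transition
  nctx <- nrow(tr)
  # context chain: ctx -> (4*ctx + b) mod nctx with prob tr[ctx, b]
  P <- matrix(0, nctx, nctx)
  for (ctx in seq_len(nctx)) {
    for (b in 0:3) {
      nxt <- ((ctx - 1L) * 4L + b) %% nctx + 1L
      P[ctx, nxt] <- P[ctx, nxt] + tr[ctx, b + 1L]
    }
  }
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  pi_ctx <- Re(e$vectors[, i]); pi_ctx <- pi_ctx / sum(pi_ctx)
  as.vector(t(tr) %*% pi_ctx)
}

#' Build a labeled synthetic benchmark corpus with a 75/25 split
#'
#' Generates `n_species` species models and `genomes_per_species`
#' genomes each, then splits the genomes of every species into training
#' and test sets, taking `floor(0.75 * g)` genomes for training
#' (rounding down, stratified by species) and the rest for testing.
#' Corpus and split are deterministic per seed; re-running with another
#' `split_seed` permutes membership only.
#'
#' @param n_species number of species (default 6).
#' @param genomes_per_species genomes per species (default 12).
#' @param genome_length genome length in bp (default 20000).
#' @param seed integer seed for models and genomes.
#' @param split_seed seed for the train/test permutation (default
#'   `seed`).
#' @param train_fraction training fraction (default 0.75).
#' @param ... passed to [sample_genome()] (`mutation_rate`,
#'   `genome_kappa`) and [make_species()] (`order`, `concentration`).
#' @return A list with `corpus` (a [seq_corpus()]), logical `is_train`,
#'   `train` / `test` corpora, and `models`.
#' @export
make_benchmark <- function(n_species = 6L, genomes_per_species = 12L,
                           genome_length = 20000L, seed = 1L,
                           split_seed = seed, train_fraction = 0.75,
                           order = 2L, concentration = 1,
                           mutation_rate = 0.02, genome_kappa = 200) {
  models <- make_species(n_species, order = order,
                         concentration = concentration, seed = seed)
  rows <- list()
  for (i in seq_along(models)) {
    for (g in seq_len(genomes_per_species)) {
      gseed <- seed + 1000L * i + g
      rows[[length(rows) + 1L]] <-
        sample_genome(models[[i]], genome_length,
                      mutation_rate = mutation_rate, seed = gseed,
                      genome_kappa = genome_kappa,
                      id = sprintf("%s_g%02d", models[[i]]$name, g))
    }
  }
  corpus <- do.call(rbind, rows)
  class(corpus) <- c("seq_corpus", "data.frame")
  is_train <- benchmark_split(corpus, split_seed, train_fraction)
  list(corpus = corpus, is_train = is_train,
       train = corpus[is_train, , drop = FALSE],
       test = corpus[!is_train, , drop = FALSE],
       models = models)
}

#' Draw a stratified train/test split of a labeled corpus
#'
#' Per species, `floor(train_fraction * g)` genomes go to training
#' (rounded down) and the rest to testing; membership is a seeded
#' permutation.
#'
#' @param corpus a [seq_corpus()] with a `species` column.
#' @param seed integer seed.
#' @param train_fraction training fraction (default 0.75).
#' @return Logical vector, `TRUE` for training rows.
#' @export
benchmark_split <- function(corpus, seed = 1L, train_fraction = 0.75) {
  is_train <- logical(nrow(corpus))
  with_seed(seed, {
    for (sp in unique(corpus$species)) {
      idx <- which(corpus$species == sp)
      n_train <- floor(train_fraction * length(idx))
      is_train[sample(idx, n_train)] <- TRUE
    }
  })
  is_train
}
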