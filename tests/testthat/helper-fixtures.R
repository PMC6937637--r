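# Shared synthetic fixtures, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

# 4 species x 6 genomes of 100 kb, chunked into 20 kb pieces and
# embedded with the default pipeline settings; used by the classifier
# and phylogeny tests.
chunked_fixture <- function() {
  fx <- .fixture_env$chunked
  if (is.null(fx)) {
    bench <- make_benchmark(n_species = 4, genomes_per_species = 6,
                            genome_length = 100000, seed = 1234)
    chunks <- chunk_genome(bench$corpus, 20000, 37)
    feats <- corpus_features(chunks)
    fit <- fit_svd(feats, 40)
    fx <- list(bench = bench, chunks = chunks, feats = feats,
               model = fit$model, vectors = fit$vectors)
    .fixture_env$chunked <- fx
  }
  fx
}

# 6 species x 12 genomes of 100 kb: feature matrices for 4/20/100 kb
# prefixes of each genome, plus 20 kb chunk features, shared by the
# recovery-protocol tests.
recovery_fixture <- function() {
  fx <- .fixture_env$recovery
  if (is.null(fx)) {
    bench <- make_benchmark(n_species = 6, genomes_per_species = 12,
                            genome_length = 100000, seed = 424242)
    corpus <- bench$corpus
    prefix_feats <- lapply(c(`4000` = 4000, `20000` = 20000,
                             `100000` = 100000), function(L) {
      pre <- corpus
      pre$sequence <- substr(pre$sequence, 1, L)
      corpus_features(pre)
    })
    chunks <- chunk_genome(corpus, 20000, 37)
    fx <- list(bench = bench, corpus = corpus,
               prefix_feats = prefix_feats,
               chunks = chunks, chunk_feats = corpus_features(chunks))
    .fixture_env$recovery <- fx
  }
  fx
}
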