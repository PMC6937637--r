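make_toy_index <- function(X, labels = NULL) {
  rownames(X) <- paste0("v", seq_len(nrow(X)))
  build_index(X, labels = labels)
}

test_that("every stored vector is its own nearest neighbor", {
  set.seed(31)
  X <- matrix(rnorm(100 * 8), 100, 8)
  idx <- make_toy_index(X)
  for (i in sample(100, 20)) {
    nn <- nearest_neighbors(idx, X[i, ], K = 1)
    expect_equal(nn$id, paste0("v", i))
    expect_lt(nn$distance, 1e-8)
  }
})

test_that("kd-tree neighbor lists equal the brute-force scan exactly", {
  set.seed(32)
  X <- matrix(rnorm(200 * 10), 200, 10)
  idx <- make_toy_index(X)
  for (j in 1:50) {
    q <- rnorm(10)
    nn <- nearest_neighbors(idx, q, K = 20)
    bf <- brute_knn(X, q, 20)
    expect_equal(nn$id, paste0("v", bf$idx))
    expect_equal(nn$distance, unname(bf$dist), tolerance = 1e-12)
    expect_true(all(diff(nn$distance) >= 0))
  }
})

test_that("duplicate-distance ties are broken by insertion order", {
  X <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1), c(5, 5))
  idx <- make_toy_index(X)
  nn <- nearest_neighbors(idx, c(0.5, 0.5), K = 4)
  expect_equal(nn$id, c("v1", "v2", "v3", "v4"))
})

test_that("K is clamped to the index size with a warning", {
  X <- matrix(rnorm(6), 3, 2)
  idx <- make_toy_index(X)
  expect_warning(nn <- nearest_neighbors(idx, c(0, 0), K = 10), "clamped")
  expect_equal(nrow(nn), 3)
  one <- build_index(matrix(c(1, 2), 1, 2), ids = "only")
  expect_equal(nearest_neighbors(one, c(0, 0), K = 1)$id, "only")
})

test_that("single-neighbor classification reads the winning label", {
  X <- rbind(c(0, 0), c(10, 10))
  idx <- build_index(X, labels = data.frame(id = c("a", "b"),
                                            species = c("spA", "spB")))
  expect_equal(classify_nn(idx, c(1, 1)), "spA")
  expect_equal(classify_nn(idx, c(9, 9)), "spB")
  expect_equal(classify_nn(idx, c(0, 0)), "spA")   # exact training vector
  idx2 <- build_index(X, labels = data.frame(id = c("a", "b"),
                                             species = c(NA, "spB")))
  expect_error(classify_nn(idx2, c(0, 0)), "has no 'species' label")
  expect_error(classify_nn(idx, c(0, 0), rank = "family"), "not present")
})

test_that("candidate pools are ordered, distinct, and contain the top-1", {
  set.seed(33)
  X <- matrix(rnorm(50 * 4), 50, 4)
  labs <- data.frame(id = paste0("v", 1:50),
                     species = sample(c("s1", "s2", "s3"), 50, replace = TRUE))
  idx <- build_index(X, labels = labs)
  for (j in 1:10) {
    q <- rnorm(4)
    pool <- candidate_pool(idx, q, K = 20)
    expect_equal(pool[1], classify_nn(idx, q))
    expect_equal(anyDuplicated(pool), 0)
  }
  # degenerate single-label index
  idx1 <- build_index(X, labels = data.frame(id = paste0("v", 1:50),
                                             species = rep("only", 50)))
  expect_equal(candidate_pool(idx1, rnorm(4), K = 20), "only")
})

test_that("majority vote counts chunk labels with distance tie-breaks", {
  X <- rbind(c(0, 0), c(0, 1), c(10, 10))
  idx <- build_index(X, labels = data.frame(id = c("x", "y", "z"),
                                            species = c("a", "a", "b")))
  # votes a, a, b -> a
  Q <- rbind(c(0, 0), c(0, 1), c(10, 10))
  expect_equal(majority_classify(idx, Q), "a")
  # tie a vs b: a's best distance smaller -> a
  Q2 <- rbind(c(0.1, 0), c(10, 11))
  expect_equal(majority_classify(idx, Q2), "a")
  # tie with equal best distances -> lexicographic
  Xe <- rbind(c(0, 0), c(2, 0))
  idxe <- build_index(Xe, labels = data.frame(id = c("p", "q"),
                                              species = c("b", "a")))
  expect_equal(majority_classify(idxe, rbind(c(0, 0), c(2, 0))), "a")
  expect_error(majority_classify(idx, X[0, , drop = FALSE]), "at least one")
})

test_that("consensus host sets honor the count threshold and ordering", {
  # 4 reference points: genera g1, g1, g2, g3 in distance order
  X <- rbind(c(0, 0), c(0, 1), c(0, 2), c(0, 3))
  idx <- build_index(X, labels = data.frame(id = paste0("b", 1:4),
                                            genus = c("g1", "g1", "g2", "g3")))
  expect_equal(consensus_hosts(idx, c(0, 0), n_neighbors = 4, min_count = 2),
               "g1")
  expect_setequal(consensus_hosts(idx, c(0, 0), n_neighbors = 4, min_count = 1),
                  c("g1", "g2", "g3"))
  expect_equal(consensus_hosts(idx, c(0, 0), n_neighbors = 4, min_count = 3),
               character(0))
  expect_error(consensus_hosts(idx, c(0, 0), n_neighbors = 1, min_count = 2),
               "n_neighbors >= min_count")
})

test_that("consensus with min_count 1 covers the candidate pool", {
  set.seed(34)
  X <- matrix(rnorm(60 * 4), 60, 4)
  labs <- data.frame(id = paste0("v", 1:60),
                     genus = sample(paste0("g", 1:5), 60, replace = TRUE))
  idx <- build_index(X, labels = labs)
  for (j in 1:5) {
    q <- rnorm(4)
    pool <- candidate_pool(idx, q, K = 15, rank = "genus")
    cons <- consensus_hosts(idx, q, n_neighbors = 15, min_count = 1)
    expect_true(all(pool %in% cons))
  }
})

test_that("neighbor-count calibration hits the target mean set size", {
  set.seed(35)
  X <- matrix(rnorm(120 * 4), 120, 4)
  labs <- data.frame(id = paste0("v", 1:120),
                     genus = sample(paste0("g", 1:6), 120, replace = TRUE))
  idx <- build_index(X, labels = labs)
  Q <- matrix(rnorm(10 * 4), 10, 4)
  # mean set size is non-decreasing in the neighbor count
  sizes <- sapply(c(4, 10, 20, 40), function(nn) {
    mean(sapply(1:10, function(i) {
      length(consensus_hosts(idx, Q[i, ], n_neighbors = nn, min_count = 2))
    }))
  })
  expect_true(all(diff(sizes) >= 0))
  n_star <- calibrate_neighbor_count(idx, Q, min_count = 2,
                                     target_avg_guesses = 3, range = 2:50)
  expect_lt(abs(attr(n_star, "mean_guesses") - 3), 0.5)
  # exact-hit construction: every query keeps the same set size
  idx1 <- build_index(X, labels = data.frame(id = paste0("v", 1:120),
                                             genus = rep("only", 120)))
  n1 <- calibrate_neighbor_count(idx1, Q, min_count = 2,
                                 target_avg_guesses = 1, range = 2:10)
  expect_equal(attr(n1, "mean_guesses"), 1)
  expect_equal(as.integer(n1), 2)         # ties resolved to the smallest n
})

test_that("evaluation percentages are plain accuracy arithmetic", {
  pred <- data.frame(query_id = c("q1", "q2", "q3"),
                     predicted = c("a", "b", "c"),
                     candidates = c("a;b", "a;c", "c;d"))
  truth <- data.frame(id = c("q1", "q2", "q3"),
                      species = c("a", "a", "c"))
  rep <- evaluate(pred, truth)
  expect_equal(rep$top1_pct, 100 * 2 / 3, tolerance = 1e-10)
  expect_equal(rep$pool_pct, 100)
  expect_true(is.na(rep$consensus_pct))
  all_ok <- evaluate(data.frame(query_id = "q1", predicted = "a"), truth)
  expect_equal(all_ok$top1_pct, 100)
  none <- evaluate(data.frame(query_id = "q1", predicted = "z"), truth)
  expect_equal(none$top1_pct, 0)
})

test_that("chunk neighbors concentrate within the source genome", {
  fx <- chunked_fixture()
  ch <- fx$chunks
  idx <- build_index(fx$vectors,
                     labels = ch[, c("id", "parent", "species", "genus")])
  same_genome <- vapply(seq_len(nrow(fx$vectors)), function(i) {
    nn <- nearest_neighbors(idx, fx$vectors[i, ], K = 2)
    ch$parent[match(nn$id[2], ch$id)] == ch$parent[i]
  }, logical(1))
  expect_gte(mean(same_genome), 0.7)
})
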