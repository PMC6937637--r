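test_that("cosine distances hit their geometric anchors", {
  V <- rbind(a = c(1, 0), b = c(2, 0), c = c(0, 3), d = c(-1, 0))
  D <- distance_matrix(V, "cosine")
  expect_equal(D["a", "b"], 0)            # parallel
  expect_equal(D["a", "c"], 1)            # orthogonal
  expect_equal(D["a", "d"], 2)            # antiparallel
  expect_true(isSymmetric(unclass(D)))
  expect_equal(diag(D), setNames(rep(0, 4), rownames(V)))
  expect_error(distance_matrix(rbind(z = c(0, 0), a = c(1, 1)), "cosine"),
               "zero vector.*z")
})

test_that("euclidean and manhattan matrices match stats::dist", {
  set.seed(41)
  V <- matrix(rnorm(12), 4, 3, dimnames = list(letters[1:4], NULL))
  expect_equal(distance_matrix(V, "euclidean")[, ],
               as.matrix(dist(V)), ignore_attr = TRUE)
  expect_equal(distance_matrix(V, "manhattan")[, ],
               as.matrix(dist(V, "manhattan")), ignore_attr = TRUE)
})

test_that("a clearly closer pair is merged first under any linkage", {
  D <- matrix(c(0, 1, 10,
                1, 0, 10,
                10, 10, 0), 3, dimnames = list(c("a", "b", "c"),
                                               c("a", "b", "c")))
  for (lk in c("average", "complete", "single")) {
    tr <- build_tree(D, lk)
    nwk <- tree_newick(tr)
    ph <- read_newick(nwk)
    # a and b form a cherry
    mrca <- ape::getMRCA(ph, c("a", "b"))
    expect_equal(sort(ape::extract.clade(ph, mrca)$tip.label), c("a", "b"))
  }
  expect_error(build_tree(D[1, 1, drop = FALSE]), "at least two")
})

test_that("ultrametric inputs give the same tree for all linkages", {
  # perfectly nested distances: pairs (a,b) and (c,d) at 2, across at 6
  D <- matrix(6, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D[cbind(c("a", "b"), c("b", "a"))] <- 2
  D[cbind(c("c", "d"), c("d", "c"))] <- 2
  diag(D) <- 0
  splits <- lapply(c("average", "complete", "single"), function(lk) {
    tree_splits_oracle(as_phylo_tree(build_tree(D, lk)))
  })
  expect_equal(splits[[1]], splits[[2]])
  expect_equal(splits[[1]], splits[[3]])
})

test_that("tree building is invariant to leaf relabeling", {
  set.seed(42)
  V <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(paste0("t", 1:6), NULL))
  D <- distance_matrix(V, "cosine")
  perm <- sample(6)
  D2 <- D[perm, perm]
  s1 <- tree_splits_oracle(as_phylo_tree(build_tree(D)))
  s2 <- tree_splits_oracle(as_phylo_tree(build_tree(D2)))
  expect_setequal(s1, s2)
})

test_that("species form monophyletic clades on the synthetic fixture", {
  fx <- chunked_fixture()
  corpus <- fx$bench$corpus
  M <- corpus_features(corpus)       # whole genomes, no chunking
  vec <- fit_svd(M, 24)$vectors      # fewer leaves than 40: r capped
  rownames(vec) <- corpus$id
  D <- distance_matrix(vec, "cosine")
  ph <- as_phylo_tree(build_tree(D, "average"))
  for (sp in unique(corpus$species)) {
    tips <- corpus$id[corpus$species == sp]
    expect_true(ape::is.monophyletic(ph, tips), info = sp)
  }
})

test_that("classical MDS reproduces Euclidean-embeddable distances", {
  # collinear points 0, 1, 3: exactly 1-D
  D <- as.matrix(dist(matrix(c(0, 1, 3), 3, 1)))
  rownames(D) <- colnames(D) <- c("p0", "p1", "p3")
  X <- classical_mds(D, 2)
  expect_equal(as.matrix(dist(X)), D, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(X[, 2])), 1e-8)       # second coordinate ~ 0
  # any 2-D point set is reproduced exactly
  set.seed(43)
  P <- matrix(rnorm(16), 8, 2)
  D2 <- as.matrix(dist(P))
  X2 <- classical_mds(D2, 2)
  expect_equal(as.matrix(dist(X2)), D2, tolerance = 1e-8, ignore_attr = TRUE)
  # duplicate points map to coincident coordinates
  P3 <- rbind(P, P[1, ])
  X3 <- classical_mds(as.matrix(dist(P3)), 2)
  expect_equal(X3[9, ], X3[1, ], tolerance = 1e-8, ignore_attr = TRUE)
  # eigenvalues non-increasing, variance fraction sane
  ev <- attr(X2, "eig")
  expect_true(all(diff(ev) <= 1e-10))
  expect_gte(attr(X2, "variance_fraction"), 1 - 1e-8)
  expect_error(classical_mds(D, 3), "more than 3 points")
})

test_that("MDS in 3 dimensions embeds 3-D configurations", {
  set.seed(44)
  P <- matrix(rnorm(18), 6, 3)
  X <- classical_mds(as.matrix(dist(P)), 3)
  expect_equal(as.matrix(dist(X)), as.matrix(dist(P)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("Robinson-Foulds matches the bipartition-enumeration oracle", {
  t_ab <- read_newick("((a,b),(c,d));")
  t_ac <- read_newick("((a,c),(b,d));")
  expect_equal(robinson_foulds(t_ab, t_ab), 0)
  expect_equal(robinson_foulds(t_ab, t_ac), 2)
  expect_equal(robinson_foulds(t_ab, t_ac), rf_oracle(t_ab, t_ac))
  set.seed(45)
  for (i in 1:10) {
    t1 <- ape::rtree(8)
    t2 <- ape::rtree(8)
    expect_equal(robinson_foulds(t1, t2), rf_oracle(t1, t2))
    # metric properties on this pair
    expect_equal(robinson_foulds(t1, t2), robinson_foulds(t2, t1))
    expect_equal(robinson_foulds(t1, t1), 0)
  }
  t_extra <- read_newick("((a,b),(c,e));")
  expect_error(robinson_foulds(t_ab, t_extra), "leaf sets differ")
})

test_that("newick export round-trips the leaf set and parses", {
  fx <- chunked_fixture()
  V <- fx$vectors[1:8, ]
  D <- distance_matrix(V, "cosine")
  f <- withr::local_tempfile(fileext = ".nwk")
  tree_newick(build_tree(D), path = f)
  ph <- read_newick(f)
  expect_setequal(ph$tip.label, rownames(V))
})
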