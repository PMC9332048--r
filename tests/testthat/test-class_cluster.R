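# Class-matrix similarity, distance and complete-linkage grouping.

toy_counts <- function(C, seed) {
  set.seed(seed)
  matrix(sample.int(30, 16 * C, TRUE), 16, C)
}

test_that("identical matrices align diagonally at the chance-corrected weight", {
  M <- toy_counts(8, 80)
  res <- matrix_similarity(M, M, matrix_align_params(seed = 1))
  # each diagonal match weighs 4S/sigma, no indels
  expect_equal(res$n_indel, 0L)
  expect_equal(res$F, 8 * 4 * res$S / res$sigma, tolerance = 1e-9)
  # column-permuted copy never beats self-similarity
  Mp <- M[, sample(ncol(M))]
  Fp <- matrix_similarity(M, Mp, matrix_align_params(seed = 1),
                          S = res$S, sigma = res$sigma)$F
  expect_lte(Fp, res$F + 1e-9)
  expect_error(matrix_similarity(M[1:4, ], M), "16 rows")
})

test_that("matrix similarity equals a direct coding of the recurrence", {
  for (r in 1:20) {
    Mn <- toy_counts(sample(3:6, 1), 200 + r)
    Mq <- toy_counts(sample(3:6, 1), 300 + r)
    S <- 10; sigma <- 4; d <- sample(c(5, 20), 1)
    got <- matrix_similarity(Mn, Mq, matrix_align_params(d = d, seed = r),
                             S = S, sigma = sigma)$F
    expect_equal(got, oracle_matrix_F(Mn, Mq, d, S, sigma),
                 tolerance = 1e-9, info = paste("pair", r))
  }
})

test_that("class distance follows the normalized similarity deficit", {
  expect_equal(class_distance(100, 80, 80), 0)
  expect_equal(class_distance(100, 80, 0), 1)
  expect_equal(class_distance(100, 80, 60), 0.25)
  expect_equal(class_distance(100, 80, 60, squared = TRUE), 0.25 / 80)
  expect_error(class_distance(0, 80, 10), "positive")
})

test_that("distance matrices are symmetric with zero self-distance", {
  Ms <- lapply(1:4, function(i) toy_counts(6, 400 + i))
  D <- class_distance_matrix(Ms, matrix_align_params(n_mix = 300, seed = 5))
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 4), rownames(D)))
  # duplicated matrices sit at distance ~0 and merge first
  D2 <- class_distance_matrix(c(Ms[1], Ms[1], Ms[3:4]),
                              matrix_align_params(n_mix = 300, seed = 5))
  expect_lt(D2[1, 2], 0.05)
  hc <- complete_linkage(D2, cut = 0.8)$hclust
  expect_setequal(abs(hc$merge[1, ]), c(1, 2))
})

test_that("complete linkage groups block structure and matches the oracle", {
  D <- matrix(0.95, 6, 6)
  D[1:3, 1:3] <- 0.1; D[4:6, 4:6] <- 0.1
  diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("c", 1:6)
  res <- complete_linkage(D, cut = 0.8)
  expect_equal(length(unique(res$groups$group)), 2L)
  expect_equal(res$groups$group[1:3], rep(res$groups$group[1], 3))

  # all-distant classes stay singletons
  Dfar <- matrix(0.95, 4, 4); diag(Dfar) <- 0
  rownames(Dfar) <- colnames(Dfar) <- paste0("c", 1:4)
  expect_equal(length(unique(complete_linkage(Dfar, 0.8)$groups$group)), 4L)

  # random 8-point distances reproduce naive-agglomeration merge heights
  set.seed(81)
  for (r in 1:5) {
    X <- matrix(runif(64), 8, 8)
    Dr <- (X + t(X)) / 2; diag(Dr) <- 0
    rownames(Dr) <- colnames(Dr) <- paste0("x", 1:8)
    hc <- complete_linkage(Dr, 0.8)$hclust
    expect_equal(sort(hc$height), oracle_linkage_heights(Dr),
                 tolerance = 1e-9)
  }

  # malformed inputs
  Dbad <- matrix(runif(16), 4, 4); diag(Dbad) <- 0
  expect_error(complete_linkage(Dbad), "symmetric")
  Dd <- matrix(0.5, 3, 3)
  expect_error(complete_linkage(Dd), "diagonal")

  # the dendrogram is valid Newick with one tip per class
  nwk <- complete_linkage(D, 0.8)$newick
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, rownames(D))
})

test_that("row-shuffled control matrices are far apart", {
  spec <- synth_spec()
  profs <- with_seed(82, lapply(1:3, function(i) synth_class_profile(spec)))
  Ms <- with_seed(83, lapply(profs, function(p)
    unclass(build_frequency_matrix(sample_class_members(p, 60, 0.10)))))
  prm <- matrix_align_params(n_mix = 400, seed = 6)
  ctl <- random_control_distances(Ms, seed = 7, params = prm)
  expect_equal(diag(ctl$D), setNames(rep(0, 3), rownames(ctl$D)))
  expect_gt(ctl$min_offdiag, 0.8)
  ctl2 <- random_control_distances(Ms, seed = 7, params = prm)
  expect_identical(ctl$D, ctl2$D)
  # the unshuffled planted-class matrices are themselves distinct classes
  D <- class_distance_matrix(Ms, prm)
  expect_gt(min(D[upper.tri(D)]), 0.5)
})
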