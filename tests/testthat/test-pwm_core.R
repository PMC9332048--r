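# Dinucleotide encoding, frequency matrices, standardized PWM,
# normalization and conservation profile.

test_that("dinucleotide encoding follows v(prev) + 4(v(cur)-1)", {
  expect_equal(encode_dinucleotides("AA")[2], 1L)
  expect_equal(encode_dinucleotides("GG")[2], 16L)
  expect_equal(encode_dinucleotides("TC")[2], 10L)
  expect_true(is.na(encode_dinucleotides("ANA")[2]))
  expect_true(is.na(encode_dinucleotides("ANA")[3]))
  # bijection over all 16 ordered pairs
  bases <- c("A", "T", "C", "G")
  s <- vapply(1:4, function(i) vapply(1:4, function(j)
    encode_dinucleotides(paste0(bases[i], bases[j]))[2], 0L), integer(4))
  expect_setequal(as.vector(s), 1:16)
})

test_that("frequency matrices count ungapped adjacent pairs", {
  M <- build_frequency_matrix(c("ACG", "ACG"))
  expect_equal(dim(M), c(16L, 2L))
  expect_equal(colnames(M), c("2", "3"))
  expect_equal(M["AC", "2"], 2L)
  expect_equal(M["CG", "3"], 2L)
  expect_equal(sum(M), 4L)

  # a gap at column 2 removes that sequence's pairs at columns 2 and 3
  A <- rbind(c("A", "C", "G"), c("A", "-", "G"))
  Mg <- build_frequency_matrix(A)
  expect_equal(sum(Mg[, "2"]), 1L)
  expect_equal(sum(Mg[, "3"]), 1L)

  expect_error(build_frequency_matrix(c("ACG", "AC")), "ragged")

  # total count equals a brute-force pair enumeration on gapped alignments
  set.seed(20)
  for (r in 1:5) {
    A <- matrix(sample(c("A", "T", "C", "G", "-", "N"), 8 * 12, TRUE,
                       prob = c(rep(.22, 4), .06, .06)), 8, 12)
    expect_equal(sum(build_frequency_matrix(A)), oracle_pair_total(A))
  }
})

test_that("standardized PWM matches a direct evaluation and edge policies", {
  # uniform counts give identically zero weights
  Mu <- matrix(5L, 16, 4)
  expect_true(all(abs(compute_pwm(Mu)$pwm) < 1e-12))

  # counts equal to expectation give zero in each constructed cell
  M <- matrix(0L, 16, 3)
  M[, 1] <- 2L * (1:16); M[, 2] <- 1:16; M[, 3] <- 3L * (1:16)
  pw <- compute_pwm(M)
  expect_true(all(abs(pw$pwm) < 1e-9))

  # 16 x 3 counts 1..48 against the independent single-pass oracle
  M2 <- matrix(1:48, 16, 3)
  expect_equal(unname(compute_pwm(M2)$pwm), oracle_pwm_prime(M2),
               tolerance = 1e-12)

  # empty column flagged and zero-weighted; zero-count row smoothed
  M3 <- matrix(3L, 16, 3); M3[, 2] <- 0L
  pw3 <- compute_pwm(M3)
  expect_equal(pw3$empty_cols, 2L)
  expect_true(all(pw3$pwm[, 2] == 0))
  M4 <- matrix(3L, 16, 3); M4[7, ] <- 0L
  pw4 <- compute_pwm(M4)
  expect_true(pw4$smoothed)
  expect_true(all(is.finite(pw4$pwm)))
})

test_that("normalization zeroes K_d and fixes R^2 = 75 L1", {
  set.seed(21)
  for (r in 1:20) {
    L1 <- sample(5:80, 1)
    W <- matrix(rnorm(16 * (L1 - 1), sd = runif(1, .5, 3)), 16, L1 - 1)
    x <- normalize_pwm(W)
    expect_lt(abs(kd_statistic(x$pwm, x$p1, x$p2)),
              1e-9 * sqrt(75 * L1))
    expect_equal(r2_statistic(x$pwm) / L1, 75, tolerance = 1e-9)
    # scale invariance of the transform
    x10 <- normalize_pwm(W * 10)
    expect_equal(x10$pwm, x$pwm, tolerance = 1e-9)
  }
  # fixed point: an already-normalized matrix passes through unchanged
  W <- matrix(rnorm(16 * 20), 16, 20)
  x1 <- normalize_pwm(W)
  x2 <- normalize_pwm(x1$pwm)
  expect_equal(x2$pwm, x1$pwm, tolerance = 1e-12)
  expect_equal(x2$norm$alpha, 1, tolerance = 1e-9)
  expect_equal(x2$norm$kappa, 0, tolerance = 1e-9)
  expect_error(normalize_pwm(matrix(2, 16, 10)), "constant")
})

test_that("PWM cells from iid-background alignments are near-standardized", {
  set.seed(22)
  aln <- replicate(1000, random_seq(60, rep(.25, 4)))
  pw <- compute_pwm(build_frequency_matrix(aln))
  cells <- as.vector(pw$pwm)
  expect_lt(abs(mean(cells)), 0.1)
  expect_lt(abs(var(cells) - 1), 0.25)
})

test_that("conservation profile transforms column sums of squares", {
  W <- matrix(0, 16, 3)
  W[, 2] <- sqrt(8.5 / 16)  # column sum of squares 8.5 -> X = 0
  X <- conservation_profile(W)
  expect_equal(X[1], -sqrt(17))
  expect_equal(X[2], 0)
  # iid-background PWMs have |X| < 4 for at least 99% of columns
  set.seed(23)
  xs <- unlist(lapply(1:100, function(r) {
    aln <- replicate(60, random_seq(25, rep(.25, 4)))
    conservation_profile(compute_pwm(build_frequency_matrix(aln)))
  }))
  expect_gt(mean(abs(xs) < 4), 0.99)
})

test_that("PWM serialization round-trips through TSV + JSON", {
  set.seed(24)
  aln <- replicate(30, random_seq(50))
  x <- normalize_pwm(compute_pwm(build_frequency_matrix(aln)))
  prefix <- tempfile()
  write_pwm(x, prefix, class_id = 7L)
  y <- read_pwm(prefix)
  expect_equal(unname(y$pwm), unname(x$pwm), tolerance = 1e-12)
  expect_equal(y$p, x$p, tolerance = 1e-12)
  expect_equal(y$L1, x$L1)
  expect_true(y$normalized)
  expect_equal(y$class_id, 7L)
})
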