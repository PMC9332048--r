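# Shuffle nulls and Z scores.

test_that("shuffles preserve the right token multisets deterministically", {
  set.seed(40)
  s <- random_seq(600)
  m <- shuffle_sequence(s, "mono", seed = 7)
  expect_equal(sort(strsplit(m, "")[[1]]), sort(strsplit(s, "")[[1]]))
  expect_identical(shuffle_sequence(s, "mono", seed = 7), m)
  expect_false(identical(m, s))

  p <- shuffle_sequence("AATTCCGG", "pair", seed = 1)
  toks <- substring(p, c(1, 3, 5, 7), c(2, 4, 6, 8))
  expect_setequal(toks, c("AA", "TT", "CC", "GG"))

  tr <- shuffle_sequence("AAATTTCCC", "triplet", seed = 1)
  toks3 <- substring(tr, c(1, 4, 7), c(3, 6, 9))
  expect_setequal(toks3, c("AAA", "TTT", "CCC"))

  # local modes preserve the window-wise token multiset on long input
  long <- random_seq(1500)
  pl <- shuffle_sequence(long, "pair", window = 600, stride = 300, seed = 2)
  expect_equal(sort(strsplit(pl, "")[[1]]), sort(strsplit(long, "")[[1]]))
  expect_identical(shuffle_sequence(long, "pair", seed = 2),
                   shuffle_sequence(long, "pair", seed = 2))
})

test_that("membership Z is studentized against the per-sequence shuffle null", {
  set.seed(41)
  aln <- replicate(80, random_seq(600))
  pwm <- normalize_pwm(compute_pwm(build_frequency_matrix(aln)))
  s <- random_seq(600)
  z1 <- z_score_membership(s, pwm, n = 200, seed = 5)
  z2 <- z_score_membership(s, pwm, n = 200, seed = 5)
  expect_identical(z1$z, z2$z)  # bit-identical under the same seed
  expect_equal(z1$null$n, 200L)
  # a sequence from the null scores near zero
  expect_lt(abs(z1$z), 4)
  # degenerate null variance is an error
  expect_error(z_score_membership(s, matrix(0, 16, 599), n = 20, seed = 1),
               "variance")
})

test_that("planted class members score Z above the membership threshold", {
  spec <- synth_spec()
  prof <- with_seed(44, synth_class_profile(spec))
  mem <- with_seed(45, sample_class_members(prof, 210, 0.10))
  pwm <- normalize_pwm(compute_pwm(build_frequency_matrix(mem[1:200])))
  z <- vapply(mem[201:210], function(s)
    z_score_membership(s, pwm, n = 100, seed = 46)$z, 0)
  expect_true(all(z > 5))
})

test_that("chromosome nulls estimate a stable window-score distribution", {
  set.seed(47)
  aln <- replicate(50, random_seq(60, rep(.25, 4)))
  pwm <- normalize_pwm(compute_pwm(build_frequency_matrix(aln)))
  chrom <- random_seq(60000, rep(.25, 4))
  n1 <- chromosome_null(chrom, pwm, n_windows = 300, seed = 1)
  n2 <- chromosome_null(chrom, pwm, n_windows = 300, seed = 2)
  se <- sqrt(n1$var / n1$n + n2$var / n2$n)
  expect_lt(abs(n1$mean - n2$mean), 5 * se)
  expect_equal(n1$window_len, 60 + 50)

  # more null windows tighten the mean estimate; the decrease is slightly
  # sub-sqrt-n because windows tile one permutation (token depletion makes
  # them negatively correlated), so only the ordering is asserted
  means_small <- vapply(1:16, function(s)
    chromosome_null(chrom, pwm, n_windows = 100, seed = s)$mean, 0)
  means_big <- vapply(1:16, function(s)
    chromosome_null(chrom, pwm, n_windows = 400, seed = 100 + s)$mean, 0)
  ratio <- sd(means_small) / sd(means_big)
  expect_gt(ratio, 1.15)
  expect_lt(ratio, 3.5)

  expect_error(chromosome_null(paste(rep("N", 200), collapse = ""), pwm,
                               n_windows = 5), "all N")
  expect_error(chromosome_null("ACGT", pwm, n_windows = 5), "shorter")
})

test_that("an iid chromosome and its shuffle give the same score law", {
  set.seed(48)
  aln <- replicate(50, random_seq(40, rep(.25, 4)))
  pwm <- normalize_pwm(compute_pwm(build_frequency_matrix(aln)))
  chrom <- random_seq(181000, rep(.25, 4))
  wlen <- 39 + 1 + 50
  direct <- cpp_scan_windows(base_codes(chrom), pwm$pwm, 20, wlen, wlen, 1)
  shuf <- with_seed(49, paste(sample(strsplit(chrom, "")[[1]]), collapse = ""))
  shuffled <- cpp_scan_windows(base_codes(shuf), pwm$pwm, 20, wlen, wlen, 1)
  ks <- suppressWarnings(stats::ks.test(direct[, "emax"], shuffled[, "emax"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("null model caches round-trip through JSON", {
  nulls <- list("1:chr1:identity" = structure(
    list(mean = 10.5, var = 2.25, n = 100L, mode = "mono", seed = 3L,
         window_len = 650L), class = "scan_null"))
  f <- tempfile(fileext = ".json")
  write_null_cache(nulls, f)
  back <- read_null_cache(f)
  expect_equal(back[["1:chr1:identity"]]$mean, 10.5)
  expect_equal(back[["1:chr1:identity"]]$var, 2.25)
})
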