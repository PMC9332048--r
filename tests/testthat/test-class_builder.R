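# Multiple alignment by PWM optimization and iterative class construction.
# GA settings are reduced (small population, few generations) so the tests
# stay fast; the aligner converges quickly on gapless-optimal inputs.

quiet_mahds <- function(...) suppressWarnings(mahds_align(...))
small_ga <- ga_params(pop_size = 2, generations = 2, sample_size = 100,
                      patience = 1)

test_that("identical sequences align gaplessly with maximal fitness", {
  set.seed(50)
  s <- random_seq(600)
  res <- quiet_mahds(rep(s, 8), ga = small_ga, seed = 1)
  expect_equal(ncol(res$V), 600L)
  expect_false(anyNA(res$V))
  expect_equal(res$candidate$L1, 600L)
  # fitness trace is non-decreasing (elitist selection)
  expect_true(all(diff(res$fitness) >= 0))
  # all rows identical
  expect_equal(nrow(unique(res$V)), 1L)
})

test_that("the aligner is deterministic under a seed", {
  set.seed(51)
  seqs <- replicate(6, random_seq(600))
  r1 <- quiet_mahds(seqs, ga = small_ga, seed = 9)
  r2 <- quiet_mahds(seqs, ga = small_ga, seed = 9)
  expect_identical(r1$V, r2$V)
  expect_identical(r1$fitness, r2$fitness)
  expect_error(mahds_align(c("ACGT", "ACG"), ga = small_ga), "equal length")
})

test_that("planted members separate from random sequences at Z > 5", {
  spec <- synth_spec()
  prof <- with_seed(52, synth_class_profile(spec))
  planted <- with_seed(53, sample_class_members(prof, 50, 0.10))
  set.seed(54)
  rand <- replicate(50, random_seq(600))
  seqs <- c(planted, rand)
  names(seqs) <- c(paste0("p", 1:50), paste0("r", 1:50))
  cls <- suppressWarnings(
    build_classes(seqs, min_class_size = 25L, n_shuffles = 60,
                  ga = ga_params(pop_size = 2, generations = 2,
                                 sample_size = 100, patience = 1),
                  seed = 55, max_classes = 1L))
  expect_equal(length(cls), 1L)
  got <- cls[[1]]$members
  expect_gt(mean(paste0("p", 1:50) %in% got), 0.9)  # planted members pass
  expect_gt(mean(!paste0("r", 1:50) %in% got), 0.9) # random sequences fail
})

test_that("build_classes handles the minimal boundary case", {
  set.seed(57)
  s <- random_seq(600)
  cls <- suppressWarnings(
    build_classes(c(a = s, b = s), min_class_size = 1L, n_shuffles = 40,
                  ga = small_ga, seed = 3))
  expect_equal(length(cls), 1L)
  expect_setequal(cls[[1]]$members, c("a", "b"))
  expect_equal(cls[[1]]$volume, 2L)
  expect_equal(attr(cls, "unassigned"), character(0))
})

test_that("accepted classes are disjoint and re-score above threshold", {
  spec <- synth_spec()
  profs <- with_seed(58, lapply(1:2, function(i) synth_class_profile(spec)))
  set.seed(59)
  seqs <- c(sample_class_members(profs[[1]], 60, 0.10),
            sample_class_members(profs[[2]], 30, 0.10),
            replicate(20, random_seq(600)))
  names(seqs) <- paste0("s", seq_along(seqs))
  cls <- suppressWarnings(
    build_classes(seqs, min_class_size = 15L, n_shuffles = 60,
                  ga = ga_params(pop_size = 2, generations = 3,
                                 sample_size = 80, patience = 1),
                  seed = 60))
  expect_gte(length(cls), 2L)
  ids <- unlist(lapply(cls, `[[`, "members"))
  expect_equal(anyDuplicated(ids), 0L)
  expect_equal(vapply(cls, `[[`, 0L, "class_id"), seq_along(cls))
  # members re-score above the threshold against their stored class PWM
  for (cl in cls) {
    z <- with_seed(61, vapply(seqs[cl$members[1:5]], function(s)
      z_score_membership(s, cl$pwm, n = 60)$z, 0))
    expect_true(all(z > 5))
  }
  # the first (largest) planted class is recovered first
  expect_gte(cls[[1]]$volume, cls[[2]]$volume)
})

test_that("shuffled control sets never reach the class-volume threshold", {
  set.seed(62)
  seqs <- replicate(80, random_seq(600))
  ctl1 <- suppressWarnings(
    random_control_classes(seqs, seed = 1, n_shuffles = 40,
                           ga = ga_params(pop_size = 2, generations = 2,
                                          sample_size = 60, patience = 1)))
  ctl2 <- suppressWarnings(
    random_control_classes(seqs, seed = 1, n_shuffles = 40,
                           ga = ga_params(pop_size = 2, generations = 2,
                                          sample_size = 60, patience = 1)))
  expect_identical(ctl1$volumes, ctl2$volumes)  # deterministic per seed
  expect_true(all(ctl1$volumes >= 0))
  expect_true(all(ctl1$volumes < 100))
})
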