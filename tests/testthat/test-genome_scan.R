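# Genome scanning: candidate extraction, overlap resolution, strand
# variants and feature intersection.

# shared small scanning fixture: one planted class in a 50-kb chromosome
scan_fix <- local({
  spec <- synth_spec()
  prof <- with_seed(70, synth_class_profile(spec))
  members <- with_seed(71, sample_class_members(prof, 120, 0.10))
  pwm <- normalize_pwm(compute_pwm(build_frequency_matrix(members[1:100])))
  set.seed(72)
  bg <- strsplit(random_seq(50000), "")[[1]]
  plant_at <- 20001L
  bg[plant_at:(plant_at + 599L)] <- strsplit(members[101], "")[[1]]
  chrom <- paste(bg, collapse = "")
  cl <- structure(list(class_id = 1L, L1 = 600L, pwm = pwm),
                  class = "promoter_class")
  null <- chromosome_null(chrom, pwm, n_windows = 500, seed = 73)
  list(chrom = chrom, cl = cl, null = null, plant = c(plant_at, plant_at + 599L),
       cfg = scan_config(stride = 10L, null_windows = 500L))
})

test_that("a planted instance yields exactly one well-localized candidate", {
  f <- scan_fix
  cands <- scan_chromosome(f$chrom, "chr1", list(f$cl),
                           list("1" = f$null), f$cfg)
  expect_equal(nrow(cands), 1L)
  ov <- min(cands$end, f$plant[2]) - max(cands$start, f$plant[1]) + 1
  expect_gte(ov / 600, 0.9)
  expect_gte(cands$Z, 6)
  expect_match(cands$alignment, "^[0-9]+[MID]")
  # an impossible threshold empties the scan
  cfg9 <- f$cfg; cfg9$z0 <- 1e9
  expect_equal(nrow(scan_chromosome(f$chrom, "chr1", list(f$cl),
                                    list("1" = f$null), cfg9)), 0L)
  # a missing null model is an error
  expect_error(scan_chromosome(f$chrom, "chr1", list(f$cl), list(), f$cfg),
               "null model")
})

test_that("overlap resolution keeps the larger Z and matches the oracle", {
  two <- data.frame(id = NA, chromosome = "c", start = c(100L, 400L),
                    end = c(699L, 999L), strand = "+", Z = c(7, 8),
                    score = c(1, 2), class_id = c(1L, 2L), alignment = "",
                    l0 = 1L, lmax = 1L, stringsAsFactors = FALSE)
  out <- resolve_overlaps(two, 0.10)  # 50% mutual overlap
  expect_equal(out$Z, 8)
  expect_equal(out$class_id, 2L)
  # 5% overlap: both survive
  two$start <- c(100L, 670L); two$end <- c(699L, 1269L)
  expect_equal(nrow(resolve_overlaps(two, 0.10)), 2L)
  # equal Z: the lower class id wins
  two$start <- c(100L, 400L); two$end <- c(699L, 999L); two$Z <- c(8, 8)
  expect_equal(resolve_overlaps(two, 0.10)$class_id, 1L)

  set.seed(74)
  for (r in 1:8) {
    n <- 30L
    st <- sample.int(5000, n)
    cand <- data.frame(id = NA, chromosome = "c", start = st,
                       end = st + sample(50:400, n, TRUE), strand = "+",
                       Z = round(runif(n, 6, 12), 2), score = 1,
                       class_id = sample.int(4, n, TRUE), alignment = "",
                       l0 = 1L, lmax = 1L, stringsAsFactors = FALSE)
    got <- resolve_overlaps(cand, 0.10)
    want <- cand[sort(oracle_resolve(cand, 0.10)), ]
    rownames(want) <- NULL
    expect_equal(got[order(got$start), ]$start, want[order(want$start), ]$start)
    expect_equal(got[order(got$start), ]$Z, want[order(want$start), ]$Z)
  }
})

test_that("strand variants map hits back to the forward frame", {
  f <- scan_fix
  # plant a reverse-complemented instance: it must surface in the
  # reverse_complement scan with forward-frame coordinates
  spec <- synth_spec()
  # reuse the class profile and member stream of the fixture PWM
  members <- with_seed(71, sample_class_members(
    with_seed(70, synth_class_profile(spec)), 120, 0.10))
  bg <- strsplit(scan_fix$chrom, "")[[1]]
  rc <- strsplit(sequence_transform(members[110], "reverse_complement"),
                 "")[[1]]
  bg[35001:35600] <- rc
  genome <- c(chr1 = paste(bg, collapse = ""))
  cfg <- scan_config(stride = 25L, null_windows = 300L)
  res <- scan_variants(genome, list(f$cl), cfg, seed = 76)
  rec <- res$records
  fwd <- rec[rec$strand == "+", ]
  rev <- rec[rec$strand == "-", ]
  expect_true(any(fwd$start <= f$plant[2] & fwd$end >= f$plant[1]))
  expect_true(any(rev$start <= 35600 & rev$end >= 35001))
  # coordinates round-trip under a double reverse transform
  r0 <- data.frame(id = "x", chromosome = "c", start = 11L, end = 30L,
                   strand = "-", Z = 7, score = 1, class_id = 1L,
                   alignment = "", stringsAsFactors = FALSE)
  r1 <- ppscan:::map_back_coords(ppscan:::map_back_coords(r0,
        "reverse_complement", 100L), "reverse_complement", 100L)
  expect_equal(r1[, c("start", "end")], r0[, c("start", "end")])
})

test_that("scan output shrinks monotonically in the Z threshold", {
  f <- scan_fix
  # synthetic candidate pool with a spread of Z values
  set.seed(77)
  st <- sample.int(30000, 60)
  cand <- data.frame(id = NA, chromosome = "c", start = st,
                     end = st + 599L, strand = "+",
                     Z = runif(60, 5, 10), score = 1,
                     class_id = sample.int(3, 60, TRUE), alignment = "",
                     stringsAsFactors = FALSE)
  kept <- lapply(c(6, 6.5, 7), function(z0)
    resolve_overlaps(cand[cand$Z >= z0, ], 0.10))
  expect_true(all(kept[[2]]$start %in% kept[[1]]$start))
  expect_true(all(kept[[3]]$start %in% kept[[2]]$start))
})

test_that("feature intersection applies fraction, mode and strand labels", {
  rec <- data.frame(id = c("P1", "P2"), chromosome = "c1",
                    start = c(100L, 5000L), end = c(699L, 5599L),
                    strand = c("+", "-"), Z = 7, score = 1, class_id = 1L,
                    alignment = "", stringsAsFactors = FALSE)
  feats <- data.frame(chrom = "c1", start = c(150L, 5500L),
                      end = c(749L, 5899L), strand = c("+", "+"),
                      feature_id = c("prom1", "sine1"),
                      stringsAsFactors = FALSE)
  hits <- intersect_features(rec, feats, 0.5, mode = "of_record")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$overlap_len, 550L)
  expect_equal(hits$fraction, 550 / 600)
  expect_equal(hits$strand_label, "++")
  # of_feature mode: denominator is the feature length
  sine <- intersect_features(rec, feats, 0.2, mode = "of_feature")
  s1 <- sine[sine$feature_id == "sine1", ]
  expect_equal(s1$fraction, 100 / 400)
  expect_equal(s1$strand_label, "+-")

  # random interval sets match an all-pairs oracle on counts
  set.seed(78)
  st <- sample.int(20000, 40)
  rec2 <- data.frame(id = paste0("r", 1:40), chromosome = "c1", start = st,
                     end = st + sample(100:500, 40, TRUE), strand = "+",
                     Z = 7, score = 1, class_id = 1L, alignment = "",
                     stringsAsFactors = FALSE)
  fs <- sample.int(20000, 40)
  feats2 <- data.frame(chrom = "c1", start = fs,
                       end = fs + sample(100:500, 40, TRUE), strand = "-",
                       feature_id = paste0("f", 1:40),
                       stringsAsFactors = FALSE)
  got <- intersect_features(rec2, feats2, 0.5, mode = "of_record")
  want <- 0L
  for (i in 1:40) for (j in 1:40) {
    ov <- min(rec2$end[i], feats2$end[j]) - max(rec2$start[i], feats2$start[j]) + 1
    lmin <- min(rec2$end[i] - rec2$start[i], feats2$end[j] - feats2$start[j]) + 1
    if (ov >= 0.5 * lmin) want <- want + 1L
  }
  expect_equal(nrow(got), want)
  expect_true(all(got$strand_label == "-+"))
})
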