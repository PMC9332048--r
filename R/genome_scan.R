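# Genome-wide PPS search: sliding-window local alignment of every class
# PWM along each chromosome, greedy extraction of non-intersecting local
# maxima, Z filtering against the shuffled-chromosome null, cross-class
# overlap resolution, strand/mirror variants, and feature intersection.

#' Scan configuration
#'
#' @param z0 Z threshold for reported PPSs (default 6.0).
#' @param stride window step in nt (default 1; the E_max(k) series is then
#'   dense, larger strides trade sensitivity for speed).
#' @param overlap_fraction cross-class resolution threshold: two records
#'   conflict when their intersection exceeds this fraction of the shorter
#'   record (default 0.10).
#' @param variants strand variants to scan: subset of "identity",
#'   "reverse_complement", "complement_only", "reverse_only". The mirror
#'   variants (complement-only / reverse-only) are controls.
#' @param max_n_frac windows with a larger N fraction are skipped.
#' @param gaps indel penalty for the local alignment.
#' @param window_slack window length is L1 + \code{window_slack}; 50 by
#'   default so indels can be absorbed.
#' @param null_windows windows per [chromosome_null()] model.
#' @return list of class \code{scan_config}.
#' @export
scan_config <- function(z0 = 6.0, stride = 1L, overlap_fraction = 0.10,
                        variants = c("identity", "reverse_complement"),
                        max_n_frac = 0.10, gaps = gap_params(),
                        window_slack = 50L, null_windows = 10000L) {
  stopifnot(z0 > 0, stride >= 1, overlap_fraction > 0, overlap_fraction <= 1,
            all(variants %in% c("identity", "reverse_complement",
                                "complement_only", "reverse_only")))
  structure(list(z0 = z0, stride = as.integer(stride),
                 overlap_fraction = overlap_fraction, variants = variants,
                 max_n_frac = max_n_frac, gaps = gaps,
                 window_slack = as.integer(window_slack),
                 null_windows = as.integer(null_windows)),
            class = "scan_config")
}

# greedy selection of non-intersecting intervals by descending score;
# ties broken by leftmost start. Returns indices of kept rows.
greedy_nonintersecting <- function(start, end, score) {
  ord <- order(-score, start)
  kept <- integer(0)
  ks <- integer(0); ke <- integer(0)
  for (i in ord) {
    if (!length(ks) || all(end[i] < ks | start[i] > ke)) {
      kept <- c(kept, i)
      ks <- c(ks, start[i]); ke <- c(ke, end[i])
    }
  }
  sort(kept)
}

#' Scan one chromosome with a set of class PWMs
#'
#' For each class, the local-alignment score E_max(k) is computed over
#' windows of length L1 + 50 advanced by \code{stride}; the best local
#' segments are reduced to non-intersecting local maxima (greedy by
#' descending score), studentized against the class's shuffled-chromosome
#' null, and kept when Z >= z0. The alignment trace of each kept maximum is
#' recomputed.
#'
#' @param chrom a single chromosome sequence.
#' @param chrom_name its name (stored in the records).
#' @param classes list of \code{promoter_class} objects (or of
#'   \code{dipwm}/matrix with a class_id attribute).
#' @param nulls named list of \code{scan_null} models, keyed by class id as
#'   a character string.
#' @param config a [scan_config()].
#' @param strand strand-variant code stored in the records ("+", "-", "c",
#'   "r").
#' @return candidate PPS record data.frame (columns id, chromosome, start,
#'   end, strand, Z, score, class_id, alignment, l0, lmax); one row per
#'   surviving per-class local maximum. Cross-class resolution is left to
#'   [resolve_overlaps()].
#' @export
scan_chromosome <- function(chrom, chrom_name, classes, nulls, config,
                            strand = "+") {
  d <- as_gap_penalty(config$gaps)
  codes <- base_codes(chrom)
  out <- list()
  for (cl in classes) {
    W <- as_pwm_matrix(cl)
    cid <- cl$class_id %||% attr(cl, "class_id") %||% NA_integer_
    null <- nulls[[as.character(cid)]]
    if (is.null(null))
      stop("missing null model for class ", cid, " on ", chrom_name)
    wlen <- ncol(W) + 1L + config$window_slack
    if (nchar(chrom) < wlen) next
    sc <- cpp_scan_windows(codes, W, d, wlen, config$stride,
                           config$max_n_frac)
    sc <- sc[sc[, "emax"] > 0 & !is.na(sc[, "i0"]), , drop = FALSE]
    if (!nrow(sc)) next
    z <- (sc[, "emax"] - null$mean) / sqrt(null$var)
    sig <- which(z >= config$z0)
    if (!length(sig)) next
    sc <- sc[sig, , drop = FALSE]
    z <- z[sig]
    # dedupe identical local maxima found from overlapping windows, then
    # extract non-intersecting maxima greedily by descending score
    key <- paste(sc[, "i0"], sc[, "imax"])
    first <- !duplicated(key)
    sc <- sc[first, , drop = FALSE]
    z <- z[first]
    keep <- greedy_nonintersecting(sc[, "i0"], sc[, "imax"], sc[, "emax"])
    sc <- sc[keep, , drop = FALSE]
    z <- z[keep]
    cig <- character(nrow(sc))
    for (r in seq_len(nrow(sc))) {
      ws <- sc[r, "wstart"]
      la <- cpp_local_align(codes[ws:(ws + wlen - 1L)], W, d, TRUE)
      cig[r] <- la$cigar
    }
    out[[length(out) + 1L]] <- data.frame(
      id = NA_character_, chromosome = chrom_name,
      start = as.integer(sc[, "i0"]), end = as.integer(sc[, "imax"]),
      strand = strand, Z = z, score = sc[, "emax"],
      class_id = as.integer(cid), alignment = cig,
      l0 = as.integer(sc[, "l0"]), lmax = as.integer(sc[, "lmax"]),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out))
    return(data.frame(id = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      strand = character(), Z = numeric(), score = numeric(),
                      class_id = integer(), alignment = character(),
                      l0 = integer(), lmax = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Resolve overlapping candidates across classes
#'
#' Processes candidates by descending Z (ties: lower class id, then
#' leftmost interval); a candidate is dropped when it overlaps an already
#' kept record by more than \code{overlap_fraction} of the shorter of the
#' two intervals. The surviving record keeps its own class id ("the PWM of
#' the best alignment is remembered").
#'
#' @param candidates candidate PPS records (from [scan_chromosome()]),
#'   possibly from several classes; resolution is per chromosome (and per
#'   strand variant).
#' @param overlap_fraction conflict threshold (default 0.10).
#' @return the surviving records.
#' @export
resolve_overlaps <- function(candidates, overlap_fraction = 0.10) {
  if (!nrow(candidates)) return(candidates)
  out <- list()
  for (grp in split(candidates,
                    paste(candidates$chromosome, candidates$strand))) {
    ord <- order(-grp$Z, grp$class_id, grp$start)
    kept <- logical(nrow(grp))
    for (i in ord) {
      ks <- grp$start[kept]; ke <- grp$end[kept]
      if (length(ks)) {
        ov <- pmin(ke, grp$end[i]) - pmax(ks, grp$start[i]) + 1
        lmin <- pmin(ke - ks + 1, grp$end[i] - grp$start[i] + 1)
        if (any(ov > overlap_fraction * lmin)) next
      }
      kept[i] <- TRUE
    }
    out[[length(out) + 1L]] <- grp[kept, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chromosome, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# map record coordinates from a transformed frame back to the forward frame
map_back_coords <- function(records, mode, chrom_len) {
  if (!nrow(records) || mode %in% c("identity", "complement_only"))
    return(records)
  s <- chrom_len - records$end + 1L
  e <- chrom_len - records$start + 1L
  records$start <- s
  records$end <- e
  records
}

#' Scan a genome for potential promoter sequences
#'
#' Runs [scan_chromosome()] for every chromosome and requested strand
#' variant, building (or reusing) one [chromosome_null()] model per
#' (class, chromosome, variant), maps coordinates of reverse-frame hits
#' back to the forward reference frame, resolves cross-class overlaps and
#' assigns record ids.
#'
#' @param genome named character vector of chromosome sequences.
#' @param classes list of \code{promoter_class} objects.
#' @param config a [scan_config()].
#' @param seed optional integer seed (drives the null models).
#' @param nulls optional precomputed null cache, keyed
#'   "class:chrom:variant"; missing entries are computed.
#' @return list: \code{records} (final PPS data.frame), \code{nulls} (the
#'   null cache used), \code{candidates} (pre-resolution records).
#' @export
scan_genome <- function(genome, classes, config = scan_config(), seed = NULL,
                        nulls = NULL) {
  nulls <- nulls %||% list()
  cands <- list()
  with_seed(seed, {
    for (chrom_name in names(genome)) {
      for (mode in config$variants) {
        tseq <- sequence_transform(genome[[chrom_name]], mode)
        cl_nulls <- list()
        for (cl in classes) {
          cid <- as.character(cl$class_id)
          key <- paste(cid, chrom_name, mode, sep = ":")
          if (is.null(nulls[[key]]))
            nulls[[key]] <- chromosome_null(
              tseq, cl, n_windows = config$null_windows, gaps = config$gaps,
              window_len = ncol(as_pwm_matrix(cl)) + 1L + config$window_slack)
          cl_nulls[[cid]] <- nulls[[key]]
        }
        rec <- scan_chromosome(tseq, chrom_name, classes, cl_nulls, config,
                               strand = variant_code(mode))
        rec <- map_back_coords(rec, mode, nchar(genome[[chrom_name]]))
        cands[[length(cands) + 1L]] <- rec
      }
    }
  })
  candidates <- if (length(cands)) do.call(rbind, cands) else
    scan_chromosome("ACGT", "x", list(), list(), config)[0, ]
  records <- resolve_overlaps(candidates, config$overlap_fraction)
  if (nrow(records))
    records$id <- sprintf("PPS%06d", seq_len(nrow(records)))
  list(records = records, nulls = nulls, candidates = candidates)
}

#' Scan all four strand/mirror variants
#'
#' Convenience wrapper around [scan_genome()] with every variant enabled:
#' identity (+), reverse complement (-), complement-only (c) and
#' reverse-only (r). The mirror variants serve as controls for strand
#' symmetry artefacts.
#'
#' @inheritParams scan_genome
#' @return as [scan_genome()]; records carry the variant in \code{strand}.
#' @export
scan_variants <- function(genome, classes, config = scan_config(),
                          seed = NULL, nulls = NULL) {
  config$variants <- c("identity", "reverse_complement", "complement_only",
                       "reverse_only")
  scan_genome(genome, classes, config, seed = seed, nulls = nulls)
}

#' Intersect PPS records with annotated features
#'
#' Reports every (record, feature) pair on the same chromosome whose
#' overlap passes \code{min_fraction} of the denominator selected by
#' \code{mode}: \code{"of_record"} uses the shorter of the two intervals
#' (the rule used for annotated-promoter matching), \code{"of_feature"}
#' uses the feature length (the rule used for SINE matching). The strand
#' label concatenates feature strand then record strand ("++", "--", "+-",
#' "-+").
#'
#' @param records PPS record data.frame.
#' @param features data.frame with columns chrom (or chromosome), start,
#'   end, strand and optionally feature_id.
#' @param min_fraction minimum overlap fraction (default 0.5).
#' @param mode denominator choice, "of_record" or "of_feature".
#' @return data.frame: chrom, pps_id, feature_id, overlap_len, fraction,
#'   strand_label.
#' @export
intersect_features <- function(records, features, min_fraction = 0.5,
                               mode = c("of_record", "of_feature")) {
  mode <- match.arg(mode)
  fchrom <- features$chrom %||% features$chromosome
  fid <- features$feature_id %||% paste0("feat", seq_len(nrow(features)))
  empty <- data.frame(chrom = character(), pps_id = character(),
                      feature_id = character(), overlap_len = integer(),
                      fraction = numeric(), strand_label = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(records) || !nrow(features)) return(empty)
  gr_r <- GenomicRanges::GRanges(records$chromosome,
                                 IRanges::IRanges(records$start, records$end))
  gr_f <- GenomicRanges::GRanges(fchrom,
                                 IRanges::IRanges(features$start, features$end))
  hits <- GenomicRanges::findOverlaps(gr_r, gr_f, ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- BiocGenerics::width(IRanges::pintersect(
    IRanges::ranges(gr_r)[qi], IRanges::ranges(gr_f)[si]))
  wr <- records$end[qi] - records$start[qi] + 1L
  wf <- features$end[si] - features$start[si] + 1L
  denom <- if (mode == "of_feature") wf else pmin(wr, wf)
  frac <- ov / denom
  keep <- frac >= min_fraction
  data.frame(
    chrom = records$chromosome[qi][keep],
    pps_id = records$id[qi][keep],
    feature_id = fid[si][keep],
    overlap_len = as.integer(ov[keep]),
    fraction = frac[keep],
    strand_label = paste0(features$strand[si][keep],
                          records$strand[qi][keep]),
    stringsAsFactors = FALSE
  )
}
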