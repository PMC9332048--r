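# Promoter-selection filters applied to the fixed-length regions before
# classification, and the derivation of homopolymer run-length thresholds
# from a reference promoter set.

#' Filter parameters for promoter selection
#'
#' The four rules: (1) the content of each nucleotide must be <= 60% of the
#' region; (2) at most one N; (3) no homopolymer run of base u longer than
#' m0(u), with defaults {A:13, T:12, C:5, G:5}; (4) G+C fraction within
#' 0.29 to 0.37. Defaults reproduce the thresholds calibrated on
#' experimentally confirmed dicot promoters.
#'
#' @param max_base_frac maximum fraction of the region any one base may
#'   occupy (rule 1).
#' @param max_n maximum number of N characters (rule 2).
#' @param m0 named integer vector of run-length thresholds per base (rule 3).
#' @param gc_min,gc_max allowed G+C fraction range (rule 4).
#' @return list of class \code{filter_params}.
#' @export
filter_params <- function(max_base_frac = 0.60, max_n = 1,
                          m0 = c(A = 13L, T = 12L, C = 5L, G = 5L),
                          gc_min = 0.29, gc_max = 0.37) {
  stopifnot(max_base_frac > 0, max_base_frac <= 1,
            max_n >= 0, gc_min >= 0, gc_max <= 1, gc_min <= gc_max,
            all(.BASES %in% names(m0)), all(m0 >= 1))
  structure(list(max_base_frac = max_base_frac, max_n = max_n,
                 m0 = m0[.BASES], gc_min = gc_min, gc_max = gc_max),
            class = "filter_params")
}

# longest run of each of A,T,C,G in one sequence (N runs count for no base)
max_runs <- function(seq) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  out <- setNames(integer(4), .BASES)
  for (b in .BASES) {
    len <- r$lengths[r$values == b]
    out[b] <- if (length(len)) max(len) else 0L
  }
  out
}

base_counts <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  vapply(c(.BASES, "N"), function(b) sum(ch == b), 0L)
}

#' Apply the promoter-selection filters
#'
#' A region is kept iff it passes all four rules of [filter_params()].
#' Decisions are made per sequence, so filtering is idempotent and
#' order-independent.
#'
#' @param regions a \code{promoter_set} data.frame (from
#'   [extract_promoters()]) or a character vector of equal-length sequences.
#' @param params a [filter_params()] object.
#' @return list with \code{kept} (same shape as input, the retained Set1)
#'   and \code{report}, a data.frame counting rejections by the first
#'   failing rule and by every failing rule.
#' @export
filter_promoters <- function(regions, params = filter_params()) {
  seqs <- if (is.data.frame(regions)) regions$seq else regions
  n <- length(seqs)
  fails <- matrix(FALSE, n, 4L,
                  dimnames = list(NULL, c("base_frac", "n_count", "runs", "gc")))
  if (n) {
    len <- nchar(seqs)
    for (i in seq_len(n)) {
      cnt <- base_counts(seqs[i])
      fails[i, "base_frac"] <- any(cnt[.BASES] / len[i] > params$max_base_frac)
      fails[i, "n_count"] <- cnt["N"] > params$max_n
      fails[i, "runs"] <- any(max_runs(seqs[i]) > params$m0)
      gc <- (cnt["C"] + cnt["G"]) / len[i]
      fails[i, "gc"] <- gc < params$gc_min || gc > params$gc_max
    }
  }
  keep <- rowSums(fails) == 0L
  first <- apply(fails, 1L, function(f) if (any(f)) which(f)[1] else NA_integer_)
  report <- data.frame(
    rule = colnames(fails),
    first_fail = vapply(1:4, function(r) sum(first == r, na.rm = TRUE), 0L),
    any_fail = colSums(fails),
    row.names = NULL
  )
  kept <- if (is.data.frame(regions)) {
    out <- regions[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else regions[keep]
  list(kept = kept, report = report)
}

#' Derive homopolymer run-length thresholds from a reference set
#'
#' For each base u, m0(u) is the smallest m >= 1 such that the fraction of
#' reference sequences containing a run of u longer than m falls below the
#' per-base probability cutoff.
#'
#' @param reference_regions character vector of reference promoter
#'   sequences (or a \code{promoter_set}).
#' @param cutoffs named numeric vector of per-base probability cutoffs in
#'   (0, 1), e.g. \code{c(A = .0424, T = .0365, C = .0111, G = .0076)}.
#' @return named integer vector m0 per base.
#' @export
derive_run_thresholds <- function(reference_regions, cutoffs) {
  seqs <- if (is.data.frame(reference_regions)) reference_regions$seq
          else reference_regions
  if (length(seqs) == 0L) stop("reference set is empty")
  stopifnot(all(.BASES %in% names(cutoffs)))
  if (any(cutoffs <= 0 | cutoffs >= 1)) stop("cutoffs must lie in (0, 1)")
  runs <- t(vapply(seqs, max_runs, setNames(integer(4), .BASES)))
  out <- setNames(integer(4), .BASES)
  for (b in .BASES) {
    m <- 1L
    while (mean(runs[, b] > m) >= cutoffs[b]) m <- m + 1L
    out[b] <- m
  }
  out
}
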