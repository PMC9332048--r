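# Shuffle-based null distributions and Z scores: the studentized alignment
# score against a Monte-Carlo null built from shuffled sequences.
# Mononucleotide shuffling is the default null everywhere; pair/triplet
# local shuffles are controls that preserve short-range base correlation.

#' Shuffle a sequence
#'
#' \code{mono} permutes all bases globally. \code{pair}/\code{triplet}
#' operate locally: a window (default 600 nt) is cut into consecutive
#' non-overlapping 2- or 3-base tokens which are permuted within the
#' window; the window is then advanced by \code{stride} (default 300) and
#' the procedure repeated, so token multisets are preserved per window. A
#' trailing fragment shorter than the token stays in place.
#'
#' @param seq a single sequence.
#' @param mode "mono", "pair" or "triplet".
#' @param window,stride window length and step for the local modes.
#' @param seed optional integer; same seed, same output.
#' @return shuffled sequence (same length, same base multiset).
#' @export
shuffle_sequence <- function(seq, mode = c("mono", "pair", "triplet"),
                             window = 600L, stride = 300L, seed = NULL) {
  mode <- match.arg(mode)
  with_seed(seed, {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(ch)
    if (mode == "mono") {
      return(paste(ch[sample.int(n)], collapse = ""))
    }
    k <- if (mode == "pair") 2L else 3L
    wstart <- 1L
    while (wstart <= n - k + 1L) {
      wend <- min(wstart + window - 1L, n)
      ntok <- (wend - wstart + 1L) %/% k
      if (ntok > 1L) {
        idx <- wstart - 1L + seq_len(ntok * k)
        tok <- matrix(ch[idx], nrow = k)
        ch[idx] <- as.vector(tok[, sample.int(ntok)])
      }
      if (wend >= n) break
      wstart <- wstart + stride
    }
    paste(ch, collapse = "")
  })
}

#' Membership Z score of a sequence against a class PWM
#'
#' Computes the global-alignment score F_max of the sequence against the
#' PWM, then the scores F_r of \code{n} independent mononucleotide shuffles
#' of the same sequence, and returns the studentized
#' \deqn{Z = (F_{max} - \bar F_r) / \sqrt{Dis(F_r)}.}
#' Sequences with Z above 5 are considered class members.
#'
#' @param seq a single sequence (conventionally 600 nt).
#' @param pwm a \code{dipwm}, class model or 16-row matrix.
#' @param gaps indel penalty ([gap_params()] or scalar).
#' @param n number of shuffles in the null (default 1000).
#' @param seed optional integer seed.
#' @return list of class \code{membership_z}: \code{z}, \code{fmax},
#'   \code{null} (mean, var, n, mode, seed).
#' @export
z_score_membership <- function(seq, pwm, gaps = gap_params(), n = 1000L,
                               seed = NULL) {
  W <- as_pwm_matrix(pwm)
  d <- as_gap_penalty(gaps)
  codes <- base_codes(seq)
  if (length(codes) < 2L) stop("sequence shorter than 2")
  fmax <- cpp_global_align(codes, W, d, FALSE)$score
  fr <- with_seed(seed, cpp_shuffled_global_scores(codes, W, d, as.integer(n)))
  v <- var(fr)
  if (!is.finite(v) || v <= 0)
    stop("degenerate shuffle null: zero variance (is the sequence trivial?)")
  structure(list(z = (fmax - mean(fr)) / sqrt(v), fmax = fmax,
                 null = list(mean = mean(fr), var = v, n = as.integer(n),
                             mode = "mono", seed = seed)),
            class = "membership_z")
}

#' Scan-score null model for one (class, chromosome) pair
#'
#' Mono-shuffles the chromosome and computes the best local-alignment score
#' E_max on up to \code{n_windows} non-overlapping windows of length
#' L1 + 50 (stride = window length, so the samples are independent); the
#' mean and variance of these scores calibrate the Z score of genome-scan
#' hits.
#'
#' @param chrom a single chromosome sequence (longer than one window).
#' @param pwm a \code{dipwm}, class model or 16-row matrix.
#' @param n_windows maximum number of null windows (default 10000).
#' @param gaps indel penalty.
#' @param seed optional integer seed.
#' @param window_len window length; default L1 + 50 for the given PWM.
#' @return list of class \code{scan_null}: mean, var, n, mode, seed,
#'   window_len.
#' @export
chromosome_null <- function(chrom, pwm, n_windows = 10000L,
                            gaps = gap_params(), seed = NULL,
                            window_len = NULL) {
  W <- as_pwm_matrix(pwm)
  d <- as_gap_penalty(gaps)
  wlen <- as.integer(window_len %||% (ncol(W) + 1L + 50L))
  if (nchar(chrom) < wlen)
    stop("chromosome shorter than one scan window (", wlen, " nt)")
  codes <- base_codes(chrom)
  if (all(is.na(codes))) stop("chromosome is all N")
  em <- with_seed(seed, {
    perm <- sample.int(length(codes))
    shuf <- codes[perm]
    sc <- cpp_scan_windows(shuf, W, d, wlen, wlen, 1.0)
    sc[, "emax"]
  })
  if (length(em) > n_windows) em <- em[seq_len(n_windows)]
  if (length(em) < 2L) stop("not enough windows for a null model")
  v <- var(em)
  if (!is.finite(v) || v <= 0) stop("degenerate scan null: zero variance")
  structure(list(mean = mean(em), var = v, n = length(em), mode = "mono",
                 seed = seed, window_len = wlen),
            class = "scan_null")
}

#' Write/read a cache of scan null models
#'
#' Null models are kept as JSON keyed by "class:chromosome:variant".
#'
#' @param nulls named list of \code{scan_null} objects.
#' @param path JSON file path.
#' @return path (write) or named list (read), invisibly for write.
#' @export
write_null_cache <- function(nulls, path) {
  jsonlite::write_json(lapply(nulls, unclass), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_null_cache
#' @export
read_null_cache <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, function(e) structure(as.list(e), class = "scan_null"))
}
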