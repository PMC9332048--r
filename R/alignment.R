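# Global and local dynamic-programming alignment of a nucleotide sequence
# against a dinucleotide PWM, with linear indel penalties.
#
# Scoring: sequence position t aligned to PWM column l contributes
# pwm(s(t-1, t), l), where the dinucleotide is formed with the actual
# previous base of the sequence (a gap does not re-pair bases across the
# indel), position 1 and N-containing pairs score 0. Each gapped position
# costs d.

#' Gap parameters for sequence-vs-PWM alignment
#'
#' A linear (per-position) indel penalty. The default of 20 mirrors the
#' only indel penalty calibrated in the matrix-vs-matrix alignment, where
#' d = 20 keeps the number of indels below 10 for typical profile pairs.
#'
#' @param d_seq nonnegative penalty per gapped position.
#' @return list of class \code{gap_params}.
#' @export
gap_params <- function(d_seq = 20) {
  stopifnot(is.numeric(d_seq), d_seq >= 0)
  structure(list(d_seq = d_seq), class = "gap_params")
}

as_gap_penalty <- function(gaps) {
  if (inherits(gaps, "gap_params")) gaps$d_seq else as.numeric(gaps)
}

#' Global alignment of a sequence against a PWM
#'
#' Needleman-Wunsch over the full sequence and all L1 - 1 informative PWM
#' columns; the score F_max is the value of the terminal DP cell.
#'
#' @param seq a single sequence over A/C/G/T/N (length >= 2).
#' @param pwm a \code{dipwm}, class model, or bare 16-row matrix.
#' @param gaps a [gap_params()] or a single penalty value.
#' @param trace return the alignment trace (CIGAR-like M/I/D string)?
#' @return list of class \code{pps_alignment}: \code{score} (F_max),
#'   \code{seq_interval}, \code{pwm_interval}, \code{cigar}.
#' @export
global_align <- function(seq, pwm, gaps = gap_params(), trace = FALSE) {
  W <- as_pwm_matrix(pwm)
  codes <- base_codes(seq)
  if (length(codes) < 2L) stop("sequence shorter than 2")
  res <- cpp_global_align(codes, W, as_gap_penalty(gaps), trace)
  structure(list(score = res$score,
                 seq_interval = c(1L, length(codes)),
                 pwm_interval = c(1L, ncol(W)),
                 cigar = res$cigar %||% NA_character_,
                 type = "global"),
            class = "pps_alignment")
}

#' Local alignment of a window against a PWM
#'
#' Smith-Waterman-style DP with the score floored at 0; reports the
#' best-scoring local segment E_max with its sequence interval (i0, imax)
#' and PWM-column interval (l0, lmax), both 1-based within the inputs.
#'
#' @inheritParams global_align
#' @param window a single sequence, conventionally of length L1 + 50.
#' @return list of class \code{pps_alignment} with \code{score} (E_max >= 0);
#'   intervals are NA when E_max = 0.
#' @export
local_align <- function(window, pwm, gaps = gap_params(), trace = TRUE) {
  W <- as_pwm_matrix(pwm)
  codes <- base_codes(window)
  if (length(codes) < 2L) stop("sequence shorter than 2")
  res <- cpp_local_align(codes, W, as_gap_penalty(gaps), trace)
  structure(list(score = res$score,
                 seq_interval = c(res$i0, res$imax),
                 pwm_interval = c(res$l0, res$lmax),
                 cigar = res$cigar,
                 type = "local"),
            class = "pps_alignment")
}

#' @export
print.pps_alignment <- function(x, ...) {
  cat(sprintf("%s alignment: score %.3f, seq [%s,%s], pwm cols [%s,%s]\n",
              x$type, x$score, x$seq_interval[1], x$seq_interval[2],
              x$pwm_interval[1], x$pwm_interval[2]))
  invisible(x)
}
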