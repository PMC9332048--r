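# Dinucleotide encoding, frequency matrices, the standardized-deviation
# position-weight matrix, its first/second-moment normalization, and the
# per-column conservation profile.
#
# Conventions: bases are coded v(A)=1, v(T)=2, v(C)=3, v(G)=4 and the
# ordered pair at alignment columns (j-1, j) is indexed
# s = v(j-1) + 4*(v(j) - 1), so an alignment of length L1 yields L1 - 1
# informative dinucleotide columns, stored as matrix columns named 2..L1.

#' Encode a sequence as dinucleotide indices
#'
#' Position j (j >= 2) carries the index s of the ordered base pair at
#' (j-1, j); position 1, and any position where either base is N, is NA.
#'
#' @param seq a single sequence over A/C/G/T/N.
#' @return integer vector of the same length as the sequence with values in
#'   1..16 (NA where undefined).
#' @export
encode_dinucleotides <- function(seq) {
  v <- base_codes(seq) + 1L
  n <- length(v)
  if (n < 1L) return(integer(0))
  s <- rep(NA_integer_, n)
  if (n >= 2L) s[2:n] <- v[1:(n - 1L)] + 4L * (v[2:n] - 1L)
  s
}

#' Build a dinucleotide frequency matrix from a multiple alignment
#'
#' Counts ordered base pairs at adjacent alignment columns over all
#' sequences; pairs in which either position is a gap ("-") or N are
#' skipped, so column sums never exceed the number of sequences.
#'
#' @param alignment an n_seq x L1 character matrix over A/C/G/T/N/"-", or a
#'   character vector of equal-length (gapless) aligned sequences.
#' @return integer matrix of class \code{dinuc_freq}, 16 rows (dinucleotide
#'   index) by L1 - 1 columns (named 2..L1), with attributes \code{L1} and
#'   \code{n_seq}.
#' @export
build_frequency_matrix <- function(alignment) {
  if (is.character(alignment) && !is.matrix(alignment)) {
    if (length(unique(nchar(alignment))) != 1L)
      stop("ragged alignment: sequences have different lengths")
    alignment <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  }
  stopifnot(is.matrix(alignment))
  L1 <- ncol(alignment)
  if (L1 < 2L) stop("alignment must have at least 2 columns")
  vc <- matrix(.CODE_LUT[utf8ToInt(paste(t(alignment), collapse = ""))] + 1L,
               nrow = nrow(alignment), byrow = TRUE)
  M <- matrix(0L, 16L, L1 - 1L, dimnames = list(.DINUCS, 2:L1))
  for (j in 2:L1) {
    s <- vc[, j - 1L] + 4L * (vc[, j] - 1L)
    s <- s[!is.na(s)]
    if (length(s)) M[, j - 1L] <- tabulate(s, nbins = 16L)
  }
  structure(M, L1 = L1, n_seq = nrow(alignment), class = "dinuc_freq")
}

#' Compute the standardized position-weight matrix from counts
#'
#' Each cell is the deviation of the observed dinucleotide count from its
#' expectation under the matrix-wide background, standardized by the
#' binomial standard deviation:
#' \deqn{PWM'(i,j) = (M(i,j) - N(j) p(i)) / \sqrt{N(j) p(i) (1 - p(i))}}
#' with \eqn{N(j)} the column sum, \eqn{p(i) = Y(i)/K} the background
#' frequency of dinucleotide i over the whole matrix. If any dinucleotide
#' has a zero total count, add-one smoothing is applied to the row totals
#' before computing p so that every p(i) lies in (0, 1). Columns with
#' \eqn{N(j) = 0} get zero weights and are flagged.
#'
#' @param M a 16 x (L1-1) count matrix (from [build_frequency_matrix()]).
#' @return object of class \code{dipwm}: list with \code{pwm} (16 x (L1-1)
#'   weights), \code{p} (background), \code{L1}, \code{smoothed},
#'   \code{empty_cols}, \code{normalized = FALSE}.
#' @export
compute_pwm <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == 16L)
  M <- unclass(M)
  storage.mode(M) <- "double"
  Nj <- colSums(M)
  Y <- rowSums(M)
  K <- sum(Y)
  if (K <= 0) stop("frequency matrix is empty")
  smoothed <- any(Y == 0)
  if (smoothed) {
    Y <- Y + 1
    K <- K + 16
  }
  p <- Y / K
  W <- (M - outer(p, Nj)) / sqrt(outer(p * (1 - p), Nj))
  empty <- which(unname(Nj) == 0)
  if (length(empty)) W[, empty] <- 0
  W <- matrix(as.numeric(W), 16L, ncol(M), dimnames = dimnames(M))
  structure(list(pwm = W, p = p, L1 = ncol(M) + 1L, smoothed = smoothed,
                 empty_cols = empty, normalized = FALSE, norm = NULL),
            class = "dipwm")
}

#' First moment (K_d) of a PWM under column/row weighting
#'
#' \deqn{K_d = \sum_i \sum_k W(i,k) p_1(i) p_2(k)}
#'
#' @param W 16 x (L1-1) weight matrix.
#' @param p1 row weights (default: uniform; the normalization uses the
#'   dinucleotide background of the source counts).
#' @param p2 column weights (default: uniform over the L1-1 columns).
#' @return scalar K_d.
#' @export
kd_statistic <- function(W, p1 = rep(1 / 16, 16), p2 = rep(1 / ncol(W), ncol(W))) {
  stopifnot(nrow(W) == length(p1), ncol(W) == length(p2))
  as.numeric(t(p1) %*% W %*% p2)
}

#' Second moment (R^2) of a PWM
#'
#' \deqn{R^2 = \sum_i \sum_j W(i,j)^2} over all 16 x (L1-1) cells.
#'
#' @param W weight matrix.
#' @return scalar R^2.
#' @export
r2_statistic <- function(W) sum(W^2)

#' Normalize a PWM to K_d = 0 and R^2 = 75 L1
#'
#' The transform is center-then-scale: subtract
#' \eqn{\kappa = K_d(PWM')} from every cell (valid because both weight
#' vectors sum to 1, this zeroes K_d exactly), then multiply by the
#' \eqn{\alpha} that fixes the sum of squares at \eqn{75 L_1}. A matrix
#' already satisfying both constraints is returned unchanged
#' (\eqn{\alpha = 1, \kappa = 0}), and the transform is invariant to input
#' scaling.
#'
#' @param x a \code{dipwm} from [compute_pwm()] or a bare 16-row matrix.
#' @param p1 row weights for K_d; defaults to the background p of the
#'   \code{dipwm} (uniform for a bare matrix).
#' @param p2 column weights for K_d; defaults to uniform over columns.
#' @return a \code{dipwm} with \code{normalized = TRUE} and a \code{norm}
#'   record (kappa, alpha, kd/r2 before and after).
#' @export
normalize_pwm <- function(x, p1 = NULL, p2 = NULL) {
  if (is.matrix(x)) x <- structure(list(pwm = x, p = NULL,
                                        L1 = ncol(x) + 1L,
                                        normalized = FALSE), class = "dipwm")
  W <- x$pwm
  L1 <- x$L1 %||% (ncol(W) + 1L)
  p1 <- p1 %||% x$p %||% rep(1 / 16, 16)
  p2 <- p2 %||% rep(1 / ncol(W), ncol(W))
  stopifnot(abs(sum(p1) - 1) < 1e-8, abs(sum(p2) - 1) < 1e-8)
  kd0 <- kd_statistic(W, p1, p2)
  r20 <- r2_statistic(W)
  Wc <- W - kd0
  r2c <- r2_statistic(Wc)
  if (r2c <= 0)
    stop("cannot normalize a constant PWM (zero variance after centering)")
  alpha <- sqrt(75 * L1 / r2c)
  Wn <- alpha * Wc
  x$pwm <- Wn
  x$p1 <- p1
  x$p2 <- p2
  x$normalized <- TRUE
  x$norm <- list(kappa = kd0, alpha = alpha,
                 kd_before = kd0, kd_after = kd_statistic(Wn, p1, p2),
                 r2_before = r20, r2_after = r2_statistic(Wn))
  x
}

#' Per-column conservation profile
#'
#' \deqn{X(j) = \sqrt{2 \sum_i PWM'(i,j)^2} - \sqrt{2n - 1}} with n = 9
#' degrees of freedom; approximately standard normal for a background
#' column, so |X| > 3-4 marks conserved positions.
#'
#' @param x a \code{dipwm} or 16-row matrix.
#' @param n_df degrees of freedom (default 9).
#' @return numeric vector X(j), one value per dinucleotide column.
#' @export
conservation_profile <- function(x, n_df = 9) {
  W <- as_pwm_matrix(x)
  sqrt(2 * colSums(W^2)) - sqrt(2 * n_df - 1)
}

#' Serialize a PWM (and optional frequency matrix) to TSV + JSON sidecar
#'
#' @param x a \code{dipwm}.
#' @param prefix output path prefix; writes \code{<prefix>.tsv} and
#'   \code{<prefix>.json}.
#' @param class_id optional class identifier stored in the sidecar.
#' @param M optional frequency matrix written as \code{<prefix>_counts.tsv}.
#' @return prefix, invisibly.
#' @export
write_pwm <- function(x, prefix, class_id = NULL, M = NULL) {
  W <- as_pwm_matrix(x)
  df <- data.frame(dinucleotide = rownames(W) %||% .DINUCS, W,
                   check.names = FALSE)
  colnames(df)[-1] <- as.character(2:(ncol(W) + 1L))
  write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- list(L1 = x$L1 %||% (ncol(W) + 1L), p = x$p,
               normalized = isTRUE(x$normalized), norm = x$norm,
               class_id = class_id)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!is.null(M)) {
    dfm <- data.frame(dinucleotide = .DINUCS, unclass(M), check.names = FALSE)
    colnames(dfm)[-1] <- as.character(2:(ncol(M) + 1L))
    write.table(dfm, paste0(prefix, "_counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(prefix)
}

#' Read a PWM written by [write_pwm()]
#' @param prefix path prefix used at write time.
#' @return a \code{dipwm}.
#' @export
read_pwm <- function(prefix) {
  df <- read.table(paste0(prefix, ".tsv"), sep = "\t", header = TRUE,
                   check.names = FALSE)
  W <- as.matrix(df[, -1, drop = FALSE])
  rownames(W) <- df[[1]]
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (!is.null(meta$p)) names(meta$p) <- rownames(W)
  structure(list(pwm = W, p = meta$p, L1 = meta$L1,
                 normalized = isTRUE(meta$normalized), norm = meta$norm,
                 class_id = meta$class_id),
            class = "dipwm")
}
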