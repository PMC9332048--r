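# Similarity and distance between class frequency matrices, and
# complete-linkage grouping of promoter classes.
#
# Two class frequency matrices M^n, M^q (16 x L1-1 counts) are compared by
# global alignment of their columns: the match weight of column i of M^n
# with column j of M^q is
#   w(i,j) = (1/4) * sum_k (S - |m^n(k,i) - m^q(k,j)|) / sigma,
# where S and sigma are the mean and standard deviation of the absolute
# element difference under random column pairing of the two matrices, so
# w is positive for column pairs more similar than chance.

#' Parameters for matrix-vs-matrix alignment
#'
#' @param d linear indel penalty (default 20, which keeps the number of
#'   indels below 10 for typical class-matrix pairs).
#' @param n_mix random column pairings used to estimate S and sigma.
#' @param seed optional integer seed for the pairing Monte Carlo.
#' @return list of class \code{matrix_align_params}.
#' @export
matrix_align_params <- function(d = 20, n_mix = 1000L, seed = NULL) {
  stopifnot(d >= 0, n_mix >= 2)
  structure(list(d = d, n_mix = as.integer(n_mix), seed = seed),
            class = "matrix_align_params")
}

#' Similarity of two class frequency matrices
#'
#' Needleman-Wunsch over the matrix columns with boundary
#' F(i,0) = -d i, F(0,j) = -d j and the chance-standardized match weight
#' described above. S and sigma are estimated by Monte Carlo over
#' \code{n_mix} random column pairings unless supplied explicitly.
#'
#' @param Mn,Mq 16-row count matrices (columns may differ in number).
#' @param params a [matrix_align_params()].
#' @param S,sigma optional precomputed standardization constants.
#' @return list: \code{F} (similarity), \code{n_indel} (indels on one
#'   optimal path), \code{S}, \code{sigma}.
#' @export
matrix_similarity <- function(Mn, Mq, params = matrix_align_params(),
                              S = NULL, sigma = NULL) {
  Mn <- unclass(Mn); Mq <- unclass(Mq)
  if (nrow(Mn) != 16L || nrow(Mq) != 16L)
    stop("class matrices must have 16 rows")
  storage.mode(Mn) <- "double"; storage.mode(Mq) <- "double"
  if (is.null(S) || is.null(sigma)) {
    est <- with_seed(params$seed, {
      ci <- sample.int(ncol(Mn), params$n_mix, replace = TRUE)
      cj <- sample.int(ncol(Mq), params$n_mix, replace = TRUE)
      abs(Mn[, ci, drop = FALSE] - Mq[, cj, drop = FALSE])
    })
    S <- S %||% mean(est)
    sigma <- sigma %||% sd(as.vector(est))
  }
  if (!is.finite(sigma) || sigma <= 0) {
    warning("degenerate column-difference distribution (sigma = 0); ",
            "match weights set to 0")
    W <- matrix(0, ncol(Mn), ncol(Mq))
  } else {
    # D[i,j] = sum_k |Mn[k,i] - Mq[k,j]|, computed row-slice by row-slice
    D <- matrix(0, ncol(Mn), ncol(Mq))
    for (k in 1:16) D <- D + abs(outer(Mn[k, ], Mq[k, ], "-"))
    W <- (16 * S - D) / (4 * sigma)
  }
  nw <- cpp_nw_matrix(W, params$d)
  list(F = nw$score, n_indel = nw$n_indel, S = S, sigma = sigma)
}

#' Distance between two classes from their similarities
#'
#' \deqn{D^{nq} = (\min(F^{nn}, F^{qq}) - F^{nq}) / \min(F^{nn}, F^{qq})}
#' which is 0 for identical classes and 1 when the cross-similarity is 0.
#' Setting \code{squared = TRUE} divides by the squared minimum instead
#' (an alternative reading of the distance; the linear form keeps D inside
#' the unit interval and matches the behaviour of shuffled-control distances).
#'
#' @param Fnn,Fqq positive self-similarities.
#' @param Fnq cross-similarity.
#' @param squared use the squared-denominator variant?
#' @return scalar distance.
#' @export
class_distance <- function(Fnn, Fqq, Fnq, squared = FALSE) {
  if (Fnn <= 0 || Fqq <= 0) stop("self-similarities must be positive")
  base <- min(Fnn, Fqq)
  if (squared) (base - Fnq) / base^2 else (base - Fnq) / base
}

#' Pairwise distance matrix for a set of class matrices
#'
#' @param Ms named list of 16-row frequency matrices (or of
#'   \code{promoter_class} objects, whose \code{M} is used).
#' @param params a [matrix_align_params()]; pairings are seeded per pair
#'   from \code{params$seed} for reproducibility.
#' @param squared passed to [class_distance()].
#' @return symmetric distance matrix with zero diagonal.
#' @export
class_distance_matrix <- function(Ms, params = matrix_align_params(),
                                  squared = FALSE) {
  Ms <- lapply(Ms, function(m) if (is.list(m) && !is.null(m$M)) m$M else m)
  n <- length(Ms)
  nm <- names(Ms) %||% as.character(seq_len(n))
  self <- numeric(n)
  pair_params <- function(k) {
    p <- params
    if (!is.null(params$seed)) p$seed <- params$seed + k
    p
  }
  for (i in seq_len(n))
    self[i] <- matrix_similarity(Ms[[i]], Ms[[i]], pair_params(i))$F
  D <- matrix(0, n, n, dimnames = list(nm, nm))
  k <- n
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    k <- k + 1L
    Fnq <- matrix_similarity(Ms[[i]], Ms[[j]], pair_params(k))$F
    D[i, j] <- D[j, i] <- class_distance(self[i], self[j], Fnq,
                                         squared = squared)
  }
  D
}

#' Complete-linkage grouping of promoter classes
#'
#' Standard agglomerative clustering with complete linkage; groups are the
#' connected components at merge height <= \code{cut} (singletons are
#' allowed).
#'
#' @param D square symmetric distance matrix with zero diagonal.
#' @param cut association level for forming groups (default 0.8).
#' @param tol symmetry tolerance.
#' @return list: \code{groups} (data.frame class_id -> group),
#'   \code{hclust} (the merge tree), \code{newick} (dendrogram with merge
#'   heights as branch lengths).
#' @export
complete_linkage <- function(D, cut = 0.8, tol = 1e-8) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > tol) stop("distance matrix is not symmetric")
  if (any(abs(diag(D)) > tol)) stop("distance matrix diagonal must be zero")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <-
      as.character(seq_len(nrow(D)))
  hc <- hclust(as.dist(D), method = "complete")
  grp <- cutree(hc, h = cut)
  list(groups = data.frame(class_id = names(grp), group = unname(grp),
                           stringsAsFactors = FALSE),
       hclust = hc,
       newick = ape::write.tree(ape::as.phylo(hc)))
}

#' Distances between row-shuffled control matrices
#'
#' Randomly permutes the rows of every class matrix independently and
#' recomputes the pairwise distances; the minimum off-diagonal control
#' distance indicates the distance scale expected in the absence of shared
#' column structure (and should exceed the grouping cut).
#'
#' @param Ms list of 16-row frequency matrices or \code{promoter_class}
#'   objects.
#' @param seed optional integer seed.
#' @param params a [matrix_align_params()].
#' @param squared passed through.
#' @return list: \code{D} (control distance matrix), \code{min_offdiag}.
#' @export
random_control_distances <- function(Ms, seed = NULL,
                                     params = matrix_align_params(),
                                     squared = FALSE) {
  Ms <- lapply(Ms, function(m) if (is.list(m) && !is.null(m$M)) m$M else m)
  with_seed(seed, {
    shuf <- lapply(Ms, function(m) m[sample.int(16L), , drop = FALSE])
    D <- class_distance_matrix(shuf, params, squared = squared)
    list(D = D, min_offdiag = min(D[upper.tri(D)]))
  })
}
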