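# Independent reference implementations ("oracles") used to validate the
# package's dynamic programming, overlap resolution, matrix similarity and
# linkage code. These are deliberately naive (exhaustive enumeration,
# all-pairs loops) and share no code with the implementations they check.

# dinucleotide match weight of aligning sequence position t (1-based) to
# PWM column l, coded directly from the v(prev) + 4*(v(cur)-1) convention
oracle_w <- function(codes, t, l, W) {
  if (t < 2) return(0)
  a <- codes[t - 1]; b <- codes[t]
  if (is.na(a) || is.na(b)) return(0)
  W[(a + 1) + 4 * b, l]
}

# exhaustive enumeration of all monotone global alignment paths
oracle_global <- function(codes, W, d) {
  n <- length(codes); C <- ncol(W)
  rec <- function(t, l) {
    if (t == n && l == C) return(0)
    best <- -Inf
    if (t < n && l < C)
      best <- max(best, oracle_w(codes, t + 1, l + 1, W) + rec(t + 1, l + 1))
    if (t < n) best <- max(best, -d + rec(t + 1, l))
    if (l < C) best <- max(best, -d + rec(t, l + 1))
    best
  }
  rec(0, 0)
}

# exhaustive enumeration of all local paths (any start, any end), floor 0
oracle_local <- function(codes, W, d) {
  n <- length(codes); C <- ncol(W)
  best <- 0
  rec <- function(t, l, acc) {
    best <<- max(best, acc)
    if (t < n && l < C) rec(t + 1, l + 1, acc + oracle_w(codes, t + 1, l + 1, W))
    if (t < n) rec(t + 1, l, acc - d)
    if (l < C) rec(t, l + 1, acc - d)
  }
  for (t0 in 0:(n - 1)) for (l0 in 0:(C - 1)) rec(t0, l0, 0)
  best
}

# iterative overlap resolution: repeatedly take the largest-Z candidate
# (ties: lower class id, then leftmost), keep it, discard all conflicting
oracle_resolve <- function(df, frac) {
  keep <- rep(FALSE, nrow(df))
  alive <- rep(TRUE, nrow(df))
  while (any(alive)) {
    idx <- which(alive)
    o <- idx[order(-df$Z[idx], df$class_id[idx], df$start[idx])][1]
    keep[o] <- TRUE
    alive[o] <- FALSE
    for (j in which(alive)) {
      ov <- min(df$end[o], df$end[j]) - max(df$start[o], df$start[j]) + 1
      lmin <- min(df$end[o] - df$start[o] + 1, df$end[j] - df$start[j] + 1)
      if (ov > frac * lmin) alive[j] <- FALSE
    }
  }
  which(keep)
}

# direct coding of the matrix-column similarity recurrence:
# boundary F(i,0) = -d*i, F(0,j) = -d*j;
# w(i,j) = (1/4) sum_k (S - |mn[k,i] - mq[k,j]|) / sigma
oracle_matrix_F <- function(Mn, Mq, d, S, sigma) {
  n <- ncol(Mn); m <- ncol(Mq)
  F <- matrix(0, n + 1, m + 1)
  for (i in 0:n) F[i + 1, 1] <- -d * i
  for (j in 0:m) F[1, j + 1] <- -d * j
  for (i in 1:n) for (j in 1:m) {
    w <- sum(S - abs(Mn[, i] - Mq[, j])) / (4 * sigma)
    F[i + 1, j + 1] <- max(F[i, j] + w, F[i, j + 1] - d, F[i + 1, j] - d)
  }
  F[n + 1, m + 1]
}

# naive complete-linkage agglomeration; returns sorted merge heights
oracle_linkage_heights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(D[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# maximum homopolymer run length per base, by a direct scan
oracle_max_run <- function(seq, base) {
  ch <- strsplit(seq, "")[[1]]
  best <- 0L; cur <- 0L
  for (x in ch) {
    cur <- if (x == base) cur + 1L else 0L
    best <- max(best, cur)
  }
  best
}

# total ungapped adjacent pairs in an alignment matrix (rows = sequences)
oracle_pair_total <- function(A) {
  tot <- 0L
  for (k in seq_len(nrow(A))) for (j in 2:ncol(A)) {
    if (A[k, j - 1] %in% c("A", "T", "C", "G") &&
        A[k, j] %in% c("A", "T", "C", "G")) tot <- tot + 1L
  }
  tot
}

# single-pass direct evaluation of the standardized PWM from counts
oracle_pwm_prime <- function(M) {
  Nj <- colSums(M); Y <- rowSums(M); K <- sum(M)
  p <- Y / K
  W <- matrix(0, 16, ncol(M))
  for (i in 1:16) for (j in seq_len(ncol(M)))
    W[i, j] <- (M[i, j] - Nj[j] * p[i]) / sqrt(Nj[j] * p[i] * (1 - p[i]))
  W
}

random_seq <- function(n, probs = c(0.335, 0.335, 0.165, 0.165)) {
  paste(sample(c("A", "T", "C", "G"), n, TRUE, prob = probs), collapse = "")
}

random_codes <- function(n) sample(0:3, n, TRUE)

codes_str <- function(codes) paste(c("A", "T", "C", "G")[codes + 1], collapse = "")

random_toy_pwm <- function(C) {
  matrix(sample(c(-1, 0, 1), 16 * C, TRUE), 16, C)
}
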