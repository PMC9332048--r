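# Multiple alignment of a promoter sample by profile optimization and the
# iterative construction of disjoint promoter classes.
#
# The aligner keeps a population of candidate alignments (gap patterns over
# the input sequences). Each individual is summarised by the normalized
# dinucleotide PWM of its alignment; its fitness is the summed global
# alignment score of the member sequences against that PWM. Individuals
# are improved by an EM-like step (realign every sequence to the current
# PWM by dynamic programming) and diversified by random column
# insertions/deletions; selection is elitist, so fitness never decreases
# across accepted generations.

#' Optimizer parameters for the multiple aligner
#'
#' @param pop_size population size (candidate alignments kept per
#'   generation).
#' @param generations generation cap.
#' @param p_insert,p_delete per-offspring probability of inserting/deleting
#'   one alignment column.
#' @param tol,patience stop when the best fitness improves by less than
#'   \code{tol} over \code{patience} consecutive generations.
#' @param sample_size number of sequences sampled from the working set per
#'   classification round (default 1000).
#' @param max_l1 maximum alignment length; 600 + 50 indel slack by default,
#'   matching the L1 + 50 scan window.
#' @return list of class \code{ga_params}.
#' @export
ga_params <- function(pop_size = 20L, generations = 200L, p_insert = 0.1,
                      p_delete = 0.1, tol = 1e-3, patience = 10L,
                      sample_size = 1000L, max_l1 = 650L) {
  stopifnot(pop_size >= 1, generations >= 1, p_insert >= 0, p_delete >= 0,
            tol > 0, patience >= 1, sample_size >= 2, max_l1 >= 600)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_insert = p_insert, p_delete = p_delete, tol = tol,
                 patience = as.integer(patience),
                 sample_size = as.integer(sample_size),
                 max_l1 = as.integer(max_l1)),
            class = "ga_params")
}

# frequency matrix from an integer-code alignment (1..4, NA = gap/N)
freq_from_codes <- function(Vc) {
  L1 <- ncol(Vc)
  M <- matrix(0L, 16L, L1 - 1L, dimnames = list(.DINUCS, 2:L1))
  for (j in 2:L1) {
    s <- Vc[, j - 1L] + 4L * (Vc[, j] - 1L)
    s <- s[!is.na(s)]
    if (length(s)) M[, j - 1L] <- tabulate(s, nbins = 16L)
  }
  structure(M, L1 = L1, n_seq = nrow(Vc), class = "dinuc_freq")
}

pwm_from_codes <- function(Vc) normalize_pwm(compute_pwm(freq_from_codes(Vc)))

# dinucleotide counts contributed by a single alignment row
row_pair_counts <- function(vrow) {
  L1 <- length(vrow)
  M <- matrix(0L, 16L, L1 - 1L)
  s <- vrow[-L1] + 4L * (vrow[-1L] - 1L)
  ok <- which(!is.na(s))
  if (length(ok)) M[cbind(s[ok], ok)] <- 1L
  M
}

# realign one coded sequence (0..3/NA) to a PWM; returns an alignment row
# of length L1 (codes 1..4, NA = gap)
realign_row <- function(codes, W, d) {
  res <- cpp_global_align(codes, W, d, TRUE)
  L1 <- ncol(W) + 1L
  row <- rep(NA_integer_, L1)
  ops <- res$cigar
  lens <- as.integer(regmatches(ops, gregexpr("[0-9]+", ops))[[1]])
  kinds <- regmatches(ops, gregexpr("[MID]", ops))[[1]]
  t <- 0L; l <- 0L; first_m_t <- NA_integer_
  for (k in seq_along(kinds)) {
    for (r in seq_len(lens[k])) {
      if (kinds[k] == "M") {
        t <- t + 1L; l <- l + 1L
        row[l + 1L] <- codes[t] + 1L
        if (is.na(first_m_t)) first_m_t <- t
      } else if (kinds[k] == "I") {
        t <- t + 1L
      } else l <- l + 1L
    }
  }
  # keep the base preceding the first matched position in column 1 so the
  # leading dinucleotide pair stays informative
  if (!is.na(first_m_t) && first_m_t >= 2L) row[1L] <- codes[first_m_t - 1L] + 1L
  row
}

mutate_alignment <- function(Vc, ga) {
  L1 <- ncol(Vc)
  if (runif(1) < ga$p_insert && L1 < ga$max_l1) {
    at <- sample.int(L1 + 1L, 1L)
    Vc <- cbind(Vc[, seq_len(at - 1L), drop = FALSE],
                matrix(NA_integer_, nrow(Vc), 1L),
                Vc[, seq(at, length.out = L1 - at + 1L), drop = FALSE])
  }
  L1 <- ncol(Vc)
  if (runif(1) < ga$p_delete && L1 > 600L) {
    at <- sample.int(L1, 1L)
    Vc <- Vc[, -at, drop = FALSE]
  }
  Vc
}

#' Multiple alignment of promoter sequences by PWM optimization
#'
#' Aligns >= 2 equal-length sequences, allowing indels (alignment length
#' L1 between the sequence length and \code{max_l1}), and returns the
#' alignment together with the candidate class model (frequency matrix and
#' normalized PWM) built from it. Deterministic under \code{seed}.
#'
#' @param seqs character vector of sequences (typically 600 nt).
#' @param ga a [ga_params()] object.
#' @param gaps indel penalty for sequence-vs-PWM alignment.
#' @param seed optional integer seed.
#' @return list: \code{V} (alignment as an integer-code matrix, NA = gap),
#'   \code{candidate} (list with L1, M, pwm), \code{fitness} (best-fitness
#'   trace), \code{converged} flag.
#' @export
mahds_align <- function(seqs, ga = ga_params(), gaps = gap_params(),
                        seed = NULL) {
  stopifnot(length(seqs) >= 2L)
  if (length(unique(nchar(seqs))) != 1L)
    stop("input sequences must have equal length")
  d <- as_gap_penalty(gaps)
  codes <- lapply(seqs, base_codes)
  with_seed(seed, {
    V0 <- do.call(rbind, lapply(codes, function(x) x + 1L))
    eval_ind <- function(Vc) {
      mod <- pwm_from_codes(Vc)
      W <- mod$pwm
      fit <- sum(vapply(codes,
                        function(x) cpp_global_align(x, W, d, FALSE)$score, 0))
      list(V = Vc, W = W, fit = fit)
    }
    pop <- list(eval_ind(V0))
    if (ga$pop_size > 1L)
      for (i in seq_len(ga$pop_size - 1L))
        pop[[i + 1L]] <- eval_ind(mutate_alignment(V0, ga))
    best_trace <- max(vapply(pop, `[[`, 0, "fit"))
    stall <- 0L
    converged <- FALSE
    for (gen in seq_len(ga$generations)) {
      offspring <- lapply(pop, function(ind) {
        Vn <- do.call(rbind,
                      lapply(codes, realign_row, W = ind$W, d = d))
        eval_ind(mutate_alignment(Vn, ga))
      })
      all_ind <- c(pop, offspring)
      ord <- order(vapply(all_ind, `[[`, 0, "fit"), decreasing = TRUE)
      pop <- all_ind[ord[seq_len(ga$pop_size)]]
      new_best <- pop[[1L]]$fit
      gain <- new_best - best_trace[length(best_trace)]
      best_trace <- c(best_trace, new_best)
      stall <- if (gain < ga$tol) stall + 1L else 0L
      if (stall >= ga$patience) { converged <- TRUE; break }
    }
    if (!converged)
      warning("aligner reached the generation cap; returning best so far")
    best <- pop[[1L]]
    mod <- pwm_from_codes(best$V)
    list(V = best$V,
         candidate = list(L1 = ncol(best$V),
                          M = freq_from_codes(best$V),
                          pwm = mod),
         fitness = best_trace, converged = converged)
  })
}

#' Iteratively build disjoint promoter classes
#'
#' Repeats: sample up to \code{sample_size} sequences from the working set,
#' align them ([mahds_align()]) to obtain a candidate PWM, score every
#' remaining sequence's membership Z ([z_score_membership()]); sequences
#' with Z above \code{z_threshold} form the class. A class is accepted (and
#' its members removed) while its volume is at least \code{min_class_size};
#' otherwise the procedure stops. Classes are numbered in creation order.
#'
#' @param set1 character vector of filtered promoter sequences (Set1);
#'   names, if present, are used as sequence ids.
#' @param z_threshold membership threshold (default 5.0).
#' @param min_class_size minimum accepted class volume (default 100).
#' @param n_shuffles shuffles per membership Z (default 1000).
#' @param ga a [ga_params()].
#' @param gaps indel penalty.
#' @param seed optional integer seed (single stream for the whole run).
#' @param max_classes safety cap on the number of classes.
#' @param loo leave-one-out scoring: a sequence that was part of the
#'   alignment sample is scored against the PWM rebuilt without its own
#'   alignment row. The candidate PWM partially fits every sampled
#'   sequence, which inflates in-sample Z by roughly
#'   \eqn{\sqrt{(L_1 - 1) \cdot 75 / (n p (1-p))} / sd(F_r)} and, when the
#'   working set is small relative to the sample, lets pure-background
#'   sequences clear the membership threshold; the correction removes that
#'   bias (default TRUE).
#' @return list of \code{promoter_class} objects (class_id, L1, M, pwm,
#'   members, member_z, volume); attributes \code{unassigned} (leftover
#'   ids) and \code{candidate_log} (per-round volumes).
#' @export
build_classes <- function(set1, z_threshold = 5.0, min_class_size = 100L,
                          n_shuffles = 1000L, ga = ga_params(),
                          gaps = gap_params(), seed = NULL,
                          max_classes = 50L, loo = TRUE) {
  ids <- names(set1) %||% as.character(seq_along(set1))
  names(set1) <- ids
  classes <- list()
  log <- data.frame(round = integer(), volume = integer(),
                    accepted = logical())
  with_seed(seed, {
    remaining <- set1
    round <- 0L
    while (length(remaining) >= 2L && length(classes) < max_classes) {
      round <- round + 1L
      n_s <- min(ga$sample_size, length(remaining))
      samp <- sample(seq_along(remaining), n_s)
      al <- mahds_align(unname(remaining[samp]), ga = ga, gaps = gaps)
      pwm <- al$candidate$pwm
      Mfull <- al$candidate$M
      row_of <- match(seq_along(remaining), samp)
      z <- vapply(seq_along(remaining), function(i) {
        pwm_i <- pwm
        if (loo && !is.na(row_of[i])) {
          Mi <- unclass(Mfull) - row_pair_counts(al$V[row_of[i], ])
          pwm_i <- normalize_pwm(compute_pwm(Mi))
        }
        z_score_membership(remaining[[i]], pwm_i, gaps = gaps,
                           n = n_shuffles)$z
      }, 0)
      names(z) <- names(remaining)
      members <- which(z > z_threshold)
      vol <- length(members)
      accepted <- vol >= min_class_size
      log <- rbind(log, data.frame(round = round, volume = vol,
                                   accepted = accepted))
      if (!accepted) break
      cid <- length(classes) + 1L
      classes[[cid]] <- structure(
        list(class_id = cid, L1 = al$candidate$L1, M = al$candidate$M,
             pwm = pwm, members = names(remaining)[members],
             member_z = unname(z[members]), volume = vol),
        class = "promoter_class")
      remaining <- remaining[-members]
    }
    structure(classes, unassigned = names(remaining), candidate_log = log)
  })
}

#' Candidate-class volumes for shuffled control sequences
#'
#' Mono-shuffles every sequence of the input set and runs single
#' classification rounds on the shuffled set; the resulting candidate
#' volumes indicate how large a "class" arises from composition alone
#' (and motivate the minimum accepted class volume).
#'
#' @param set1 character vector of promoter sequences.
#' @param seed optional integer seed.
#' @param rounds number of independent control rounds.
#' @param z_threshold,n_shuffles,ga,gaps,loo as in [build_classes()].
#' @return list: \code{volumes} (per round), \code{mean}, \code{sd}.
#' @export
random_control_classes <- function(set1, seed = NULL, rounds = 1L,
                                   z_threshold = 5.0, n_shuffles = 1000L,
                                   ga = ga_params(), gaps = gap_params(),
                                   loo = TRUE) {
  with_seed(seed, {
    vols <- integer(rounds)
    for (r in seq_len(rounds)) {
      shuf <- vapply(set1, shuffle_sequence, "", mode = "mono",
                     USE.NAMES = FALSE)
      n_s <- min(ga$sample_size, length(shuf))
      samp <- sample(seq_along(shuf), n_s)
      al <- mahds_align(shuf[samp], ga = ga, gaps = gaps)
      Mfull <- al$candidate$M
      row_of <- match(seq_along(shuf), samp)
      z <- vapply(seq_along(shuf), function(i) {
        pwm_i <- al$candidate$pwm
        if (loo && !is.na(row_of[i])) {
          Mi <- unclass(Mfull) - row_pair_counts(al$V[row_of[i], ])
          pwm_i <- normalize_pwm(compute_pwm(Mi))
        }
        z_score_membership(shuf[[i]], pwm_i, gaps = gaps, n = n_shuffles)$z
      }, 0)
      vols[r] <- sum(z > z_threshold)
    }
    list(volumes = vols, mean = mean(vols),
         sd = if (rounds > 1L) sd(vols) else NA_real_)
  })
}
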