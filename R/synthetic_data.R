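# Seeded generator of synthetic genomes with planted promoter classes.
#
# Each planted class is an inhomogeneous first-order Markov profile over
# the 600-nt promoter window: per column j and previous base b, the
# distribution of the next base is a Dirichlet draw centred on the
# background composition. The Dirichlet concentration controls the
# sharpness (lower = sharper); a window around the annotated start is made
# sharper than the flanks to emulate the conserved start-proximal core
# seen in real promoter classes. Members are chain samples with iid
# substitution noise, rejection-sampled so that every planted member
# passes the promoter-selection filters by construction.

#' Specification of a synthetic study genome
#'
#' Defaults define the reference validation conditions used throughout the
#' package: one ~1.2-Mb chromosome, three planted promoter classes of
#' 600/300/150 members at 15% substitution noise, 200 background genes
#' (annotated genes with no planted promoter) and 30 intergenic decoy
#' instances, background composition GC = 0.33 (within the promoter
#' filter range).
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param gc background G+C fraction.
#' @param markov_order background order: 0 (iid) or 1 (supply
#'   \code{transition}, a 4x4 row-stochastic matrix over A,T,C,G).
#' @param transition optional 4x4 transition matrix for order 1.
#' @param class_members planted members per class (vector; its length sets
#'   the number of classes).
#' @param mutation_rate per-base substitution probability applied to each
#'   member.
#' @param conc_flank,conc_core Dirichlet concentrations of the class
#'   profiles outside/inside the conserved core (lower = sharper).
#' @param core 1-based column interval of the conserved core.
#' @param n_background_genes annotated genes with background promoters.
#' @param n_decoys planted instances away from any annotated gene.
#' @param upstream,downstream promoter window geometry (600 nt total).
#' @param min_gap minimum spacing between planted windows, nt.
#' @param seed integer master seed.
#' @return list of class \code{synth_spec}.
#' @export
synth_spec <- function(chrom_lengths = c(chr1 = 1200000L),
                       gc = 0.33, markov_order = 0L, transition = NULL,
                       class_members = c(600L, 300L, 150L),
                       mutation_rate = 0.15,
                       conc_flank = 1.6, conc_core = 0.8,
                       core = c(480L, 520L),
                       n_background_genes = 200L, n_decoys = 30L,
                       upstream = 500L, downstream = 100L,
                       min_gap = 40L, seed = 1L) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1, gc > 0, gc < 1,
            all(chrom_lengths >= upstream + downstream + 100L),
            markov_order %in% c(0L, 1L), conc_flank > 0, conc_core > 0,
            all(class_members >= 1L))
  if (markov_order == 1L && is.null(transition))
    stop("markov_order 1 requires a transition matrix")
  p_bg <- c(A = (1 - gc) / 2, T = (1 - gc) / 2, C = gc / 2, G = gc / 2)
  structure(list(chrom_lengths = chrom_lengths, gc = gc, p_bg = p_bg,
                 markov_order = as.integer(markov_order),
                 transition = transition,
                 class_members = as.integer(class_members),
                 mutation_rate = mutation_rate,
                 conc_flank = conc_flank, conc_core = conc_core,
                 core = as.integer(core),
                 n_background_genes = as.integer(n_background_genes),
                 n_decoys = as.integer(n_decoys),
                 upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 min_gap = as.integer(min_gap), seed = as.integer(seed)),
            class = "synth_spec")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Draw a planted-class profile
#'
#' Samples the per-column conditional base distributions of one class.
#' Drawn within the current RNG stream (seed via \code{set.seed()} or
#' [synth_generate()]).
#'
#' @param spec a [synth_spec()] (geometry/sharpness/composition are used).
#' @return object of class \code{synth_profile}: list with \code{cond}, a
#'   4 x 4 x (L-1) array (previous base x next base x column), and the
#'   window length \code{L}.
#' @export
synth_class_profile <- function(spec = synth_spec()) {
  L <- spec$upstream + spec$downstream
  repeat {
    cond <- array(0, dim = c(4L, 4L, L - 1L))
    for (j in seq_len(L - 1L)) {
      conc <- if (j + 1L >= spec$core[1] && j + 1L <= spec$core[2])
        spec$conc_core else spec$conc_flank
      for (b in 1:4) cond[b, , j] <- rdirichlet1(conc * 4 * spec$p_bg)
    }
    # stationary-ish GC of the profile; redraw profiles whose drift would
    # push members against the GC filter
    gc_prof <- mean(apply(cond, 3L, function(m) sum(spec$p_bg %*% m * c(0, 0, 1, 1))))
    if (gc_prof >= spec$gc - 0.025 && gc_prof <= spec$gc + 0.025) break
  }
  structure(list(cond = cond, L = L, p_bg = spec$p_bg), class = "synth_profile")
}

# one chain sample from a profile (integer codes 1..4)
profile_chain <- function(profile) {
  L <- profile$L
  b <- integer(L)
  b[1] <- sample.int(4L, 1L, prob = profile$p_bg)
  for (j in 2:L)
    b[j] <- sample.int(4L, 1L, prob = profile$cond[b[j - 1L], , j - 1L])
  b
}

#' Sample noisy members of a planted class
#'
#' Chain samples from the profile with iid substitutions at
#' \code{mutation_rate}; each member is rejection-sampled (up to 50
#' attempts) until it passes the promoter-selection filters, so planted
#' members never fail [filter_promoters()] under default parameters.
#'
#' @param profile a \code{synth_profile}.
#' @param n number of members.
#' @param mutation_rate per-base substitution probability.
#' @param params filters the members must pass.
#' @return character vector of n member sequences.
#' @export
sample_class_members <- function(profile, n, mutation_rate,
                                 params = filter_params()) {
  out <- character(n)
  for (i in seq_len(n)) {
    for (try in 1:50) {
      b <- profile_chain(profile)
      mut <- which(runif(profile$L) < mutation_rate)
      if (length(mut))
        b[mut] <- 1L + (b[mut] - 1L + sample.int(3L, length(mut),
                                                 replace = TRUE)) %% 4L
      seq <- paste(.BASES[b], collapse = "")
      if (passes_filters(seq, params)) break
      if (try == 50) stop("could not sample a filter-passing member")
    }
    out[i] <- seq
  }
  out
}

passes_filters <- function(seq, params) {
  cnt <- base_counts(seq)
  len <- nchar(seq)
  if (any(cnt[.BASES] / len > params$max_base_frac)) return(FALSE)
  if (cnt["N"] > params$max_n) return(FALSE)
  if (any(max_runs(seq) > params$m0)) return(FALSE)
  gc <- (cnt["C"] + cnt["G"]) / len
  gc >= params$gc_min && gc <= params$gc_max
}

background_chrom <- function(len, spec) {
  if (spec$markov_order == 0L) {
    b <- sample.int(4L, len, replace = TRUE, prob = spec$p_bg)
  } else {
    b <- integer(len)
    b[1] <- sample.int(4L, 1L, prob = spec$p_bg)
    for (t in 2:len) b[t] <- sample.int(4L, 1L, prob = spec$transition[b[t - 1L], ])
  }
  b
}

#' Generate a synthetic genome with planted promoter classes
#'
#' Builds the background genome, draws one profile per class, places the
#' planted members as the promoter windows of annotated genes on both
#' strands (reverse-strand instances are reverse-complemented in the
#' genome), adds background genes and intergenic decoy instances, and
#' returns the truth table of every planted interval. Deterministic per
#' \code{spec$seed}: the same spec yields byte-identical FASTA/GFF3/TSV.
#'
#' @param spec a [synth_spec()].
#' @param dir optional directory; when given, writes \code{genome.fa},
#'   \code{genes.gff3} and \code{truth.tsv} there.
#' @return list: \code{genome} (named character), \code{genes} (data.frame
#'   gene_id, chrom, start, end, strand, tss), \code{truth} (data.frame
#'   chrom, start, end, strand, class_id, kind, gene_id), \code{profiles}
#'   (list of \code{synth_profile}), \code{spec}.
#' @export
synth_generate <- function(spec = synth_spec(), dir = NULL) {
  L <- spec$upstream + spec$downstream
  n_classes <- length(spec$class_members)
  with_seed(spec$seed, {
    profiles <- lapply(seq_len(n_classes), function(i) synth_class_profile(spec))

    # planted/background units to place: class members + background genes
    # (as genes) and decoys (no gene)
    units <- data.frame(
      class_id = c(rep(seq_len(n_classes), spec$class_members),
                   rep(NA_integer_, spec$n_background_genes),
                   if (spec$n_decoys)
                     sample(seq_len(n_classes), spec$n_decoys, replace = TRUE)),
      kind = c(rep("promoter", sum(spec$class_members)),
               rep("background", spec$n_background_genes),
               rep("decoy", spec$n_decoys)),
      stringsAsFactors = FALSE
    )
    units <- units[sample.int(nrow(units)), , drop = FALSE]
    units$strand <- sample(c("+", "-"), nrow(units), replace = TRUE)

    # allocate units to chromosomes proportionally to length
    n_units <- nrow(units)
    chrom_of <- rep(names(spec$chrom_lengths),
                    round(n_units * spec$chrom_lengths /
                            sum(spec$chrom_lengths)))[seq_len(n_units)]
    chrom_of[is.na(chrom_of)] <- names(spec$chrom_lengths)[1]

    genome <- character(0)
    genes <- list()
    truth <- list()
    gene_i <- 0L
    for (cn in names(spec$chrom_lengths)) {
      len <- spec$chrom_lengths[[cn]]
      b <- background_chrom(len, spec)
      u <- units[chrom_of == cn, , drop = FALSE]
      n_u <- nrow(u)
      need <- n_u * (L + spec$min_gap) + 100L
      if (need > len)
        stop("infeasible spec: ", n_u, " planted windows do not fit in ",
             cn, " (", len, " nt)")
      # random extra spacing on top of the minimum gap
      extra <- len - 100L - n_u * (L + spec$min_gap)
      cuts <- sort(runif(n_u)) * extra
      starts <- 50L + round(cuts) + (seq_len(n_u) - 1L) * (L + spec$min_gap) +
        spec$min_gap
      for (k in seq_len(n_u)) {
        s <- as.integer(starts[k]); e <- s + L - 1L
        if (u$kind[k] != "background") {
          member <- sample_class_members(profiles[[u$class_id[k]]], 1L,
                                         spec$mutation_rate)
          ins <- if (u$strand[k] == "+") member else
            sequence_transform(member, "reverse_complement")
          b[s:e] <- match(strsplit(ins, "", fixed = TRUE)[[1]], .BASES)
        }
        gid <- NA_character_
        if (u$kind[k] != "decoy") {
          gene_i <- gene_i + 1L
          gid <- sprintf("g%05d", gene_i)
          tss <- if (u$strand[k] == "+") s + spec$upstream else
            s + spec$downstream - 1L
          gs <- if (u$strand[k] == "+") tss else max(1L, tss - 199L)
          ge <- if (u$strand[k] == "+") min(len, tss + 199L) else tss
          genes[[length(genes) + 1L]] <- data.frame(
            gene_id = gid, chrom = cn, start = gs, end = ge,
            strand = u$strand[k], tss = tss, stringsAsFactors = FALSE)
        }
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = cn, start = s, end = e, strand = u$strand[k],
          class_id = u$class_id[k], kind = u$kind[k], gene_id = gid,
          stringsAsFactors = FALSE)
      }
      genome[cn] <- paste(.BASES[b], collapse = "")
    }
    genes <- do.call(rbind, genes)
    truth <- do.call(rbind, truth)
    out <- list(genome = genome, genes = genes, truth = truth,
                profiles = profiles, spec = spec)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_genome(genome, file.path(dir, "genome.fa"))
      write_genes_gff3(genes, file.path(dir, "genes.gff3"))
      write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    out
  })
}
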