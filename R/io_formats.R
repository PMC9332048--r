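# Reading genomes and gene annotations, promoter-region extraction,
# strand/mirror sequence transforms, and the flat-file PPS database
# writers (TSV / BED6 / GFF3).

#' Read a genome from FASTA
#'
#' Sequences are uppercased and any IUPAC code outside A/C/G/T is mapped to
#' N. Record names are truncated at the first whitespace and must be unique;
#' empty records are rejected.
#'
#' @param path path to a FASTA file.
#' @return A named character vector, one uppercase sequence per chromosome.
#' @export
read_genome <- function(path) {
  first <- readLines(path, n = 50L)
  nonblank <- which(nzchar(trimws(first)))
  if (length(nonblank) == 0L)
    stop("malformed FASTA at line 1: file is empty")
  if (!startsWith(trimws(first[nonblank[1]]), ">"))
    stop("malformed FASTA at line ", nonblank[1], ": expected '>' header")
  x <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(x) == 0L))
    stop("empty FASTA record: ", names(x)[Biostrings::width(x) == 0L][1])
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm))
    stop("duplicate FASTA record name: ", nm[duplicated(nm)][1])
  seqs <- toupper(as.character(x))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- nm
  seqs
}

#' Read gene annotations from GFF3
#'
#' Keeps features of type \code{gene} and records, per gene, the coordinate
#' taken as the transcription start proxy: the \code{start} column for
#' \code{+} genes and the \code{end} column for \code{-} genes (GFF3 stores
#' intervals with start <= end regardless of strand).
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns gene_id, chrom, start, end, strand, tss.
#' @export
read_genes <- function(path) {
  g <- rtracklayer::import(path)
  g <- g[S4Vectors::mcols(g)$type == "gene"]
  if (length(g) == 0L) stop("no 'gene' features in ", path)
  strand <- as.character(BiocGenerics::strand(g))
  if (any(!strand %in% c("+", "-")))
    stop("gene annotation contains strand other than +/-")
  id <- S4Vectors::mcols(g)$ID
  if (is.null(id)) id <- paste0("gene", seq_along(g))
  st <- BiocGenerics::start(g)
  en <- BiocGenerics::end(g)
  data.frame(
    gene_id = as.character(id),
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = st, end = en, strand = strand,
    tss = ifelse(strand == "+", st, en),
    stringsAsFactors = FALSE
  )
}

#' Extract fixed-length promoter regions around annotated gene starts
#'
#' For each gene the window from -\code{upstream}+1 to +\code{downstream}
#' around the annotated start (position +1) is taken on the gene's own
#' strand: a forward gene with start \eqn{t} yields the genomic interval
#' \eqn{[t - upstream, t + downstream - 1]}; a reverse gene yields
#' \eqn{[t - downstream + 1, t + upstream]} and the stored sequence is the
#' reverse complement, so every promoter reads 5' to 3' towards its gene
#' with the annotated start at position \code{upstream + 1}. Windows that
#' run off a chromosome end are dropped (not clipped) and reported in the
#' \code{"dropped"} attribute.
#'
#' @param genome named character vector as from [read_genome()].
#' @param genes data.frame as from [read_genes()] (columns gene_id, chrom,
#'   strand and tss; start/end are accepted in place of tss).
#' @param upstream,downstream window extent in nt; the default 500 + 100
#'   gives the 600-nt region spanning -499..+100.
#' @return data.frame (class \code{promoter_set}) with columns gene_id,
#'   chrom, start, end, strand, seq; attribute \code{dropped} lists genes
#'   whose window left the chromosome.
#' @export
extract_promoters <- function(genome, genes, upstream = 500, downstream = 100) {
  if (is.null(genes$tss)) {
    if (is.null(genes$start) || is.null(genes$end))
      stop("genes must have a 'tss' or 'start'/'end' columns")
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  }
  miss <- setdiff(unique(genes$chrom), names(genome))
  if (length(miss))
    stop("gene chromosome absent from genome: ", paste(miss, collapse = ", "))
  fwd <- genes$strand == "+"
  s <- ifelse(fwd, genes$tss - upstream, genes$tss - downstream + 1)
  e <- ifelse(fwd, genes$tss + downstream - 1, genes$tss + upstream)
  clen <- nchar(genome)[genes$chrom]
  ok <- s >= 1 & e <= clen
  dropped <- genes[!ok, c("gene_id", "chrom", "strand"), drop = FALSE]
  k <- which(ok)
  seqs <- substr(genome[genes$chrom[k]], s[k], e[k])
  rev <- !fwd[k]
  seqs[rev] <- sequence_transform(seqs[rev], "reverse_complement")
  out <- data.frame(
    gene_id = genes$gene_id[k], chrom = genes$chrom[k],
    start = s[k], end = e[k], strand = genes$strand[k],
    seq = unname(seqs), stringsAsFactors = FALSE
  )
  class(out) <- c("promoter_set", "data.frame")
  attr(out, "dropped") <- dropped
  out
}

#' Strand and mirror transforms of nucleotide sequences
#'
#' Besides the usual reverse complement, the two "mirror" controls are
#' supported: complement-only (base substitution without the 180-degree
#' flip) and reverse-only (the flip without complementing).
#'
#' @param seq character vector of sequences over A/C/G/T/N.
#' @param mode one of "identity", "reverse_complement", "complement_only",
#'   "reverse_only".
#' @return character vector of transformed sequences (length preserved,
#'   N maps to N).
#' @export
sequence_transform <- function(seq,
                               mode = c("identity", "reverse_complement",
                                        "complement_only", "reverse_only")) {
  mode <- match.arg(mode)
  if (length(seq) == 0L) return(seq)
  comp <- function(x) chartr("ACGTN", "TGCAN", x)
  revs <- function(x) vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), "",
                             USE.NAMES = FALSE)
  switch(mode,
    identity = seq,
    complement_only = comp(seq),
    reverse_only = revs(seq),
    reverse_complement = revs(comp(seq))
  )
}

# strand-variant codes used in PPS records:
#   "+" identity, "-" reverse_complement, "c" complement_only, "r" reverse_only
variant_code <- function(mode) {
  switch(mode, identity = "+", reverse_complement = "-",
         complement_only = "c", reverse_only = "r",
         stop("unknown variant: ", mode))
}

.PPS_COLS <- c("id", "chromosome", "start", "end", "strand", "Z", "score",
               "class_id", "alignment")

validate_pps <- function(records) {
  if (nrow(records)) {
    missing <- setdiff(.PPS_COLS, names(records))
    if (length(missing))
      stop("PPS records missing columns: ", paste(missing, collapse = ", "))
    if (any(records$start > records$end)) stop("PPS record with start > end")
  }
  records[, .PPS_COLS, drop = FALSE]
}

#' Export PPS records to TSV, BED6 or GFF3
#'
#' The TSV columns are id, chromosome, start, end, strand, Z, score,
#' class_id, alignment (CIGAR-like M/I/D trace); coordinates are 1-based
#' inclusive. BED output is 0-based half-open with \code{round(100 * Z)}
#' clamped to 1000 in the score slot. GFF3 rows use type \code{promoter}
#' with \code{class_id} and \code{Z} attributes. Strand codes other than
#' +/- (the mirror controls "c" and "r") are written as "." in BED/GFF3.
#'
#' @param records PPS record data.frame (possibly empty).
#' @param path output file path.
#' @param format one of "tsv", "bed", "gff3".
#' @param header optional character vector of comment lines (written with a
#'   leading "#") recording provenance such as seed and configuration hash.
#' @return path, invisibly.
#' @export
export_pps <- function(records, path, format = c("tsv", "bed", "gff3"),
                       header = NULL) {
  format <- match.arg(format)
  records <- validate_pps(as.data.frame(records))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "gff3") writeLines("##gff-version 3", con)
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (format == "tsv") {
    writeLines(paste(.PPS_COLS, collapse = "\t"), con)
    if (nrow(records))
      write.table(records, con, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
  } else if (format == "bed") {
    if (nrow(records)) {
      bed <- data.frame(
        records$chromosome, records$start - 1L, records$end, records$id,
        pmin(round(100 * records$Z), 1000),
        ifelse(records$strand %in% c("+", "-"), records$strand, ".")
      )
      write.table(bed, con, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
  } else {
    if (nrow(records)) {
      attrs <- sprintf("ID=%s;class_id=%s;Z=%.6g", records$id,
                       records$class_id, records$Z)
      gff <- data.frame(
        records$chromosome, "ppscan", "promoter", records$start, records$end,
        sprintf("%.6g", records$score),
        ifelse(records$strand %in% c("+", "-"), records$strand, "."),
        ".", attrs
      )
      write.table(gff, con, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a PPS TSV written by [export_pps()]
#'
#' @param path file path.
#' @return PPS record data.frame.
#' @export
read_pps <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                  colClasses = c(id = "character", chromosome = "character",
                                 strand = "character", class_id = "integer",
                                 alignment = "character"),
                  stringsAsFactors = FALSE)
  validate_pps(x)
}

#' Write a genome as FASTA
#' @param genome named character vector.
#' @param path output path.
#' @param width line width.
#' @return path, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write gene annotations as GFF3
#' @param genes data.frame with gene_id, chrom, start, end, strand.
#' @param path output path.
#' @return path, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    rows <- data.frame(genes$chrom, "ppscan", "gene", genes$start, genes$end,
                       ".", genes$strand, ".", paste0("ID=", genes$gene_id))
    write.table(rows, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
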