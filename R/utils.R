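# Internal helpers: base coding and RNG scoping.
#
# Base codes follow the {A,T,C,G} -> {1,2,3,4} convention used throughout
# the dinucleotide machinery; internally the C++ layer uses 0..3 with -1/NA
# for N. The dinucleotide index of the ordered pair (prev, cur) is
# s = v(prev) + 4 * (v(cur) - 1), giving rows AA, TA, CA, GA, AT, ... GG.

.BASES <- c("A", "T", "C", "G")

.DINUCS <- as.vector(outer(.BASES, .BASES, function(a, b) paste0(a, b)))

.CODE_LUT <- local({
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A")] <- 0L
  lut[utf8ToInt("T")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut
})

# character string -> integer codes 0..3, NA for N/other
base_codes <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  .CODE_LUT[utf8ToInt(seq)]
}

codes_to_seq <- function(codes) {
  ch <- c(utf8ToInt("A"), utf8ToInt("T"), utf8ToInt("C"), utf8ToInt("G"))
  out <- ch[codes + 1L]
  out[is.na(out)] <- utf8ToInt("N")
  intToUtf8(out)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# if seed is NULL the current RNG stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Extract the 16 x (L1-1) weight/count matrix from the containers accepted
# by the alignment and scanning functions.
as_pwm_matrix <- function(x) {
  if (is.list(x) && !is.null(x$pwm)) {
    x <- x$pwm
    if (is.list(x) && !is.null(x$pwm)) x <- x$pwm  # class model holding a dipwm
  }
  if (!is.matrix(x) || nrow(x) != 16L)
    stop("expected a 16-row dinucleotide PWM matrix")
  storage.mode(x) <- "double"
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
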