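# Internal helpers shared across modules. All user-facing coordinates in this
# package are 0-based and half-open; cut_index is the number of bases 5' of
# the break.

.DNA <- c("A", "C", "G", "T")

.is_dna <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && grepl("^[ACGT]+$", x)
}

.assert_dna <- function(x, arg = deparse(substitute(x))) {
  if (!.is_dna(x)) {
    stop("`", arg, "` must be a non-empty uppercase ACGT string (N and ",
         "other IUPAC codes are rejected)", call. = FALSE)
  }
  invisible(x)
}

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of a DNA string
#'
#' @param seq Uppercase ACGT string.
#' @return The reverse complement, as a string.
#' @examples
#' revcomp("ACGGT")
#' @export
revcomp <- function(seq) {
  .assert_dna(seq)
  chartr("ACGT", "TGCA", paste(rev(.chars(seq)), collapse = ""))
}

# Longest common prefix / suffix length of two character vectors.
.lcp <- function(a, b) {
  m <- min(length(a), length(b))
  if (m == 0L) return(0L)
  neq <- which(a[seq_len(m)] != b[seq_len(m)])
  if (length(neq) == 0L) m else neq[1L] - 1L
}

.lcs <- function(a, b) .lcp(rev(a), rev(b))

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
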