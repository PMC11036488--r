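#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   readDNAStringSet writeXStringSet
#' @importFrom stats rpois rgeom runif
#' @importFrom utils read.csv write.csv read.delim write.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

lox_error <- function(msg, class = "lox_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

lox_io_error <- function(msg) lox_error(msg, class = c("lox_io_error", "lox_error"))

#' Reverse complement of a DNA string
#'
#' @param x character scalar of ACGTN bases.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

is_acgt <- function(x) !grepl("[^ACGT]", x)

check_dna <- function(x, what = "sequence", allow_n = FALSE) {
  if (!is.character(x) || length(x) != 1L || !nzchar(x))
    lox_error(sprintf("%s must be a non-empty character scalar", what))
  x <- toupper(x)
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  if (grepl(pat, x))
    lox_error(sprintf("%s contains characters outside %s", what,
                      if (allow_n) "ACGTN" else "ACGT"))
  x
}

gc_fraction <- function(x) {
  b <- charToRaw(x)
  sum(b == charToRaw("G") | b == charToRaw("C")) / length(b)
}

# Evaluate expr with a private RNG state seeded from `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Scan a query for approximate matches of a short pattern
#'
#' Counts Hamming mismatches of `pattern` against every forward-strand offset
#' of `query` using vectorized byte comparison (one pass per pattern
#' position). This is the primitive behind motif scanning, in-silico PCR and
#' off-target screening.
#'
#' @param query,pattern uppercase DNA character scalars.
#' @param max_mismatch maximum Hamming distance reported.
#' @return data.frame with 0-based `start` and `mismatches`.
#' @keywords internal
hamming_hits <- function(query, pattern, max_mismatch = 0L) {
  q <- charToRaw(query)
  p <- charToRaw(pattern)
  n <- length(q)
  m <- length(p)
  if (m > n)
    return(data.frame(start = integer(0), mismatches = integer(0)))
  k <- n - m + 1L
  mm <- integer(k)
  for (i in seq_len(m))
    mm <- mm + (q[i:(k + i - 1L)] != p[i])
  keep <- which(mm <= max_mismatch)
  data.frame(start = keep - 1L, mismatches = mm[keep])
}
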