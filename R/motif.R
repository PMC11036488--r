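#' The default loxPsym recombination motif
#'
#' loxPsym is a 34 bp palindromic variant of the Cre recombinase loxP site.
#' Because it equals its own reverse complement, Cre recombination between two
#' loxPsym copies is orientation-independent, and a single forward-strand scan
#' finds every genomic copy.
#'
#' @param name label for the motif.
#' @param sequence motif sequence (ACGT only, length >= 8).
#' @return an object of class `lox_motif` with fields `name`, `sequence`,
#'   `length` and `is_palindromic`.
#' @examples
#' m <- lox_motif()
#' m$is_palindromic  # TRUE
#' @export
lox_motif <- function(name = "loxPsym",
                      sequence = "ATAACTTCGTATAATGTACATTATACGAAGTTAT") {
  sequence <- toupper(sequence)
  if (!is_acgt(sequence))
    lox_error("invalid motif: sequence must contain only ACGT")
  if (nchar(sequence) < 8L)
    lox_error("invalid motif: minimum length is 8 bp")
  structure(list(name = name,
                 sequence = sequence,
                 length = nchar(sequence),
                 is_palindromic = identical(sequence, revcomp(sequence))),
            class = "lox_motif")
}

#' @export
print.lox_motif <- function(x, ...) {
  cat(sprintf("<lox_motif> %s (%d bp%s)\n  %s\n", x$name, x$length,
              if (x$is_palindromic) ", palindromic" else "", x$sequence))
  invisible(x)
}

#' Find all motif occurrences in a chromosome sequence
#'
#' Scans the forward strand for exact copies of the motif. A palindromic motif
#' (such as loxPsym) has identical occurrences on both strands, so a single
#' forward scan already reports every site exactly once. Overlapping
#' occurrences (possible for repetitive user motifs, impossible for loxPsym)
#' are resolved leftmost-greedy. Circular sequences are scanned on the
#' doubled sequence so origin-spanning occurrences are found; positions are
#' reported modulo the sequence length and deduplicated.
#'
#' @param sequence DNA character scalar (uppercased on load; N tolerated).
#' @param motif a [lox_motif()].
#' @param topology `"linear"` or `"circular"`.
#' @return data.frame of 0-based half-open intervals (`start`, `end`), sorted.
#' @export
scan_motifs <- function(sequence, motif = lox_motif(), topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  sequence <- check_dna(sequence, "sequence", allow_n = TRUE)
  if (!inherits(motif, "lox_motif")) motif <- lox_motif(sequence = motif)
  L <- nchar(sequence)
  if (motif$length > L)
    lox_error("motif longer than sequence")
  subject <- if (topology == "circular") paste0(sequence, sequence) else sequence
  hits <- hamming_hits(subject, motif$sequence, 0L)$start
  if (topology == "circular") {
    hits <- sort(unique(hits[hits < L]))
  }
  # leftmost-greedy resolution of overlaps
  starts <- integer(0)
  last_end <- -1L
  for (s in hits) {
    if (s >= last_end) {
      starts <- c(starts, s)
      last_end <- s + motif$length
    }
  }
  if (topology == "circular" && length(starts) >= 2L) {
    # a wrapping occurrence may overlap the first linear one
    wrap <- starts + motif$length > L
    if (any(wrap) && (starts[which(wrap)[1L]] + motif$length - L) > starts[1L])
      starts <- starts[!wrap]
  }
  data.frame(start = starts, end = starts + motif$length)
}
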