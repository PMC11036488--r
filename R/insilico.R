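#' Find all approximate binding sites of a primer in a query
#'
#' Reports every position on both strands where the primer matches with at
#' most `max_mismatch` Hamming mismatches (mismatches are counted uniformly
#' along the primer; assemblies are error-containing, which is why mismatch
#' tolerance exists at all). A `"+"` hit means the query forward strand reads
#' as the primer there (extension rightward); a `"-"` hit means it reads as
#' the primer's reverse complement (extension leftward). Circular queries are
#' scanned on the doubled sequence; positions are reported modulo the length
#' and deduplicated, so origin-straddling sites are found exactly once.
#'
#' @param query DNA character scalar.
#' @param primer DNA character scalar.
#' @param max_mismatch Hamming threshold.
#' @param topology `"linear"` or `"circular"`.
#' @return data.frame of 0-based `start`, `strand`, `mismatches`.
#' @export
find_primer_sites <- function(query, primer, max_mismatch = 2L,
                              topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  query <- toupper(query)
  primer <- check_dna(primer, "primer")
  L <- nchar(query)
  if (nchar(primer) > L) lox_error("primer longer than query")
  subject <- if (topology == "circular") paste0(query, query) else query
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else revcomp(primer)
    h <- hamming_hits(subject, pat, max_mismatch)
    if (topology == "circular") {
      h <- h[h$start < L, , drop = FALSE]
    }
    if (nrow(h))
      out[[length(out) + 1L]] <- data.frame(start = h$start, strand = strand,
                                            mismatches = h$mismatches,
                                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out) %||%
    data.frame(start = integer(0), strand = character(0), mismatches = integer(0))
  res[order(res$start, res$strand), , drop = FALSE]
}

#' Predict end-point PCR amplicons for one primer pair on one query
#'
#' An amplicon is reported for every combination of a forward-primer hit on
#' one strand with a reverse-primer hit on the opposite strand, downstream in
#' amplifiable orientation (sites non-overlapping on the template), with
#' total length at most `max_amplicon`. Both template orientations are
#' considered, so detection is strand-symmetric: reverse-complementing the
#' query never changes the presence call. Presence is 1 iff at least one
#' amplicon exists (end-point PCR cannot distinguish multiplicity; all
#' amplicons are recorded for diagnostics).
#'
#' @param query DNA character scalar (e.g., a de novo assembly).
#' @param pair one row of a panel `pairs` data.frame (or a list with
#'   `fwd_seq`/`rev_seq`).
#' @param max_amplicon maximum amplicon size in bp (default 1000).
#' @param max_mismatch per-primer mismatch tolerance (default 2).
#' @param topology query topology; circular amplicons may cross the origin.
#' @return list with `present` (0/1) and `amplicons` data.frame
#'   (`start`, `end`, `strand`, `mm_fwd`, `mm_rev`; 0-based, `end` may
#'   exceed the query length for origin-crossing circular amplicons).
#' @export
predict_amplicons <- function(query, pair, max_amplicon = 1000L, max_mismatch = 2L,
                              topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  fwd <- toupper(pair$fwd_seq); rev <- toupper(pair$rev_seq)
  if (!nzchar(fwd) || !nzchar(rev)) lox_error("pair has empty primer sequences")
  if (max_amplicon < nchar(fwd) + nchar(rev))
    lox_error("max_amplicon smaller than the two primers")
  query <- toupper(query)
  L <- nchar(query)
  fh <- find_primer_sites(query, fwd, max_mismatch, topology)
  rh <- find_primer_sites(query, rev, max_mismatch, topology)
  amps <- list()
  add_amps <- function(left, left_len, right, right_len, strand, mm_left, mm_right) {
    # left: plus-strand hit starts (extension rightward); right: minus-strand
    # hit starts. On "-" amplicons the rev primer is the left partner, so
    # mm_fwd/mm_rev are swapped accordingly.
    for (a in seq_along(left)) {
      s1 <- left[a]; e1 <- s1 + left_len
      s2 <- right; e2 <- right + right_len
      if (topology == "circular") {
        wrap <- s2 < e1
        s2[wrap] <- s2[wrap] + L; e2[wrap] <- e2[wrap] + L
      }
      ok <- s2 >= e1 & (e2 - s1) <= max_amplicon
      if (topology == "circular") ok <- ok & (e2 - s1) <= L
      if (any(ok))
        amps[[length(amps) + 1L]] <<- data.frame(
          start = s1, end = e2[ok], strand = strand,
          mm_fwd = if (strand == "+") mm_left[a] else mm_right[ok],
          mm_rev = if (strand == "+") mm_right[ok] else mm_left[a],
          stringsAsFactors = FALSE)
    }
  }
  fp <- fh[fh$strand == "+", ]; fm <- fh[fh$strand == "-", ]
  rp <- rh[rh$strand == "+", ]; rm <- rh[rh$strand == "-", ]
  # canonical orientation: fwd on +, rev on - downstream
  add_amps(fp$start, nchar(fwd), rm$start, nchar(rev), "+", fp$mismatches, rm$mismatches)
  # inverted template: rev on +, fwd on - downstream
  add_amps(rp$start, nchar(rev), fm$start, nchar(fwd), "-", rp$mismatches, fm$mismatches)
  amps <- do.call(rbind, amps) %||%
    data.frame(start = integer(0), end = integer(0), strand = character(0),
               mm_fwd = integer(0), mm_rev = integer(0))
  amps <- unique(amps)
  list(present = as.integer(nrow(amps) > 0L), amplicons = amps)
}

#' Genotype samples against a primer panel (binary presence matrix)
#'
#' Runs [predict_amplicons()] for every (sample, junction) combination and
#' assembles the 0/1 genotype matrix: rows are samples, columns are junction
#' ids in reference panel order. Optionally writes the TSV table and a
#' two-color heatmap.
#'
#' @param samples named character vector of query sequences.
#' @param panel a `lox_panel`.
#' @param max_amplicon,max_mismatch settings as in [predict_amplicons()].
#' @param topology topology of the sample sequences.
#' @param tsv,heatmap optional output paths.
#' @return integer matrix with dimnames (samples x junctions).
#' @export
genotype <- function(samples, panel, max_amplicon = 1000L, max_mismatch = 2L,
                     topology = c("linear", "circular"),
                     tsv = NULL, heatmap = NULL) {
  topology <- match.arg(topology)
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    lox_error("samples must be named")
  if (anyDuplicated(names(samples))) lox_error("duplicate sample names")
  pr <- panel$pairs
  if (nrow(pr) == 0L) lox_error("empty panel")
  mat <- matrix(0L, nrow = length(samples), ncol = nrow(pr),
                dimnames = list(names(samples), pr$junction_id))
  for (si in seq_along(samples)) {
    for (pi in seq_len(nrow(pr))) {
      mat[si, pi] <- predict_amplicons(samples[[si]], pr[pi, ], max_amplicon,
                                       max_mismatch, topology)$present
    }
  }
  if (!is.null(tsv)) write_genotype_matrix(mat, tsv)
  if (!is.null(heatmap)) write_genotype_heatmap(mat, heatmap)
  mat
}
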