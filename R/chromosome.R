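#' Segment a chromosome into loxP units (LUs)
#'
#' LUs are the stretches of sequence between consecutive motif copies — the
#' atomic unit of SCRaMbLE rearrangement. All coordinates are 0-based
#' half-open. For a linear chromosome with n motif sites there are n + 1 LUs
#' (LU0 runs from position 0 to the first site; the last LU runs to the
#' sequence end). For a circular chromosome there are exactly n LUs and LU0
#' begins immediately after the first motif site, wrapping at the origin.
#' Zero-length LUs (adjacent motif copies) are legal and flagged.
#'
#' @param sequence chromosome sequence.
#' @param motif_sites data.frame of `start`/`end` intervals, as from
#'   [scan_motifs()].
#' @param topology `"linear"` or `"circular"`.
#' @return data.frame with `index`, `id` ("LU<k>"), `start`, `end`, `length`,
#'   `zero_length` and `sequence` columns. Circular LUs that wrap the origin
#'   have `end < start`; `sequence` is always the correct unit sequence.
#' @export
segment_units <- function(sequence, motif_sites, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  n <- nrow(motif_sites)
  if (topology == "circular" && n == 0L)
    lox_error("circular segmentation requires at least one motif site (no junction)")
  if (n > 0 && (is.unsorted(motif_sites$start, strictly = TRUE) ||
                any(motif_sites$start < 0) || any(motif_sites$end > L)))
    lox_error("motif_sites must be sorted and within the sequence")
  circ_sub <- function(s, e) {
    if (e >= s) substr(sequence, s + 1L, e)
    else paste0(substr(sequence, s + 1L, L), substr(sequence, 1L, e))
  }
  if (topology == "linear") {
    starts <- c(0L, motif_sites$end)
    ends <- c(motif_sites$start, L)
  } else {
    starts <- motif_sites$end
    ends <- c(motif_sites$start[-1L], motif_sites$start[1L])
  }
  seqs <- mapply(circ_sub, starts, ends)
  lens <- ifelse(ends >= starts, ends - starts, L - starts + ends)
  data.frame(index = seq_along(starts) - 1L,
             id = paste0("LU", seq_along(starts) - 1L),
             start = starts, end = ends, length = as.integer(lens),
             zero_length = lens == 0L,
             sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Annotate a chromosome: motif sites plus LU segmentation
#'
#' @param name sequence label.
#' @param sequence DNA character scalar (lowercase/softmasked input is
#'   uppercased).
#' @param motif a [lox_motif()].
#' @param topology `"linear"` or `"circular"`.
#' @return `lox_chromosome` object: `name`, `sequence`, `topology`, `motif`,
#'   `motif_sites` (0-based half-open data.frame), `lus` (see
#'   [segment_units()]).
#' @examples
#' chr <- generate_fixture(n_lus = 4, lu_length_range = c(200, 300), seed = 1)
#' chr$lus$id
#' @export
annotate_chromosome <- function(name, sequence, motif = lox_motif(),
                                topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  sequence <- check_dna(sequence, "sequence", allow_n = TRUE)
  sites <- scan_motifs(sequence, motif, topology)
  structure(list(name = name, sequence = sequence, topology = topology,
                 motif = motif, motif_sites = sites,
                 lus = segment_units(sequence, sites, topology)),
            class = "lox_chromosome")
}

#' @export
print.lox_chromosome <- function(x, ...) {
  cat(sprintf("<lox_chromosome> %s: %d bp, %s, %d x %s, %d LUs\n",
              x$name, nchar(x$sequence), x$topology,
              nrow(x$motif_sites), x$motif$name, nrow(x$lus)))
  invisible(x)
}

#' Signed LU arrangements
#'
#' An arrangement is the genotype at LU granularity: an ordered list of LU
#' ids with orientations (+1 forward, -1 inverted) relative to a reference
#' chromosome. Ids may repeat (duplications) or be absent (deletions).
#'
#' @param lu_ids character vector of LU ids (must exist on the reference).
#' @param orientations integer vector of +1/-1, recycled.
#' @param topology inherited topology.
#' @param source reference chromosome name.
#' @return `lox_arrangement` object with a `units` data.frame
#'   (`lu_id`, `orientation`).
#' @export
lu_arrangement <- function(lu_ids, orientations = 1L,
                           topology = c("linear", "circular"), source = NA_character_) {
  topology <- match.arg(topology)
  orientations <- as.integer(rep_len(orientations, length(lu_ids)))
  if (!all(orientations %in% c(-1L, 1L)))
    lox_error("orientations must be +1 or -1")
  structure(list(topology = topology, source = source,
                 units = data.frame(lu_id = as.character(lu_ids),
                                    orientation = orientations,
                                    stringsAsFactors = FALSE)),
            class = "lox_arrangement")
}

#' @export
print.lox_arrangement <- function(x, ...) {
  u <- x$units
  cat(sprintf("<lox_arrangement> %s, %d units: %s\n", x$topology, nrow(u),
              paste0(ifelse(u$orientation < 0, "-", ""), u$lu_id, collapse = " ")))
  invisible(x)
}

#' Identity arrangement of a reference chromosome
#' @param chromosome a `lox_chromosome`.
#' @return the arrangement listing every LU forward, in reference order.
#' @export
identity_arrangement <- function(chromosome) {
  lu_arrangement(chromosome$lus$id, 1L, chromosome$topology, chromosome$name)
}

#' Realize an LU arrangement as a DNA sequence
#'
#' The inverse of segmentation: concatenates LU sequences in arrangement
#' order, reverse-complementing inverted units, with one motif copy between
#' consecutive units (and, for circular arrangements, between the last and
#' first unit — rendering starts at the first listed unit). Deleting one LU
#' therefore shortens the render by `lu_length + motif_length`; an inversion
#' preserves length and motif count; a tandem duplication adds
#' `lu_length + motif_length`.
#'
#' @param arrangement a `lox_arrangement`.
#' @param reference the annotated reference chromosome providing LU sequences.
#' @return DNA character scalar.
#' @export
render_arrangement <- function(arrangement, reference) {
  u <- arrangement$units
  if (nrow(u) == 0L) lox_error("cannot render an empty arrangement")
  idx <- match(u$lu_id, reference$lus$id)
  if (anyNA(idx))
    lox_error(sprintf("unknown LU id(s): %s",
                      paste(u$lu_id[is.na(idx)], collapse = ", ")))
  seqs <- reference$lus$sequence[idx]
  flip <- u$orientation < 0L
  seqs[flip] <- vapply(seqs[flip], function(s)
    if (nzchar(s)) revcomp(s) else s, character(1))
  m <- reference$motif$sequence
  body <- paste(seqs, collapse = m)
  if (arrangement$topology == "circular") paste0(body, m) else body
}
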