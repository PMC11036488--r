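#' Generate a synthetic Sc2.0-style chromosome fixture
#'
#' Builds a chromosome of `n_lus` random LUs separated by single motif copies,
#' emulating a synthetic yeast chromosome in which a loxPsym site follows most
#' nonessential genes. LU sequences are i.i.d. random DNA at the requested GC
#' content; any candidate LU that would create a spurious motif occurrence
#' (on either strand, or chimerically across a junction) is rejected and
#' redrawn, so the motif census equals the number of junctions by
#' construction. Deterministic for a fixed seed.
#'
#' @param n_lus number of LUs (>= 2 linear, >= 1 circular).
#' @param lu_length_range integer 2-vector, min/max LU length in bp.
#' @param motif a [lox_motif()].
#' @param topology `"linear"` or `"circular"`.
#' @param gc GC fraction of the random LU sequence.
#' @param seed RNG seed.
#' @param name chromosome name.
#' @return an annotated `lox_chromosome`.
#' @examples
#' chr <- generate_fixture(n_lus = 12, lu_length_range = c(500, 800), seed = 7)
#' nrow(chr$motif_sites)  # 11
#' @export
generate_fixture <- function(n_lus, lu_length_range = c(500, 800),
                             motif = lox_motif(),
                             topology = c("linear", "circular"),
                             gc = 0.40, seed = 1L, name = "fixture") {
  topology <- match.arg(topology)
  min_needed <- if (topology == "linear") 2L else 1L
  if (n_lus < min_needed)
    lox_error(sprintf("%s fixture needs at least %d LUs (no junction otherwise)",
                      topology, min_needed))
  if (lu_length_range[1] < 0 || lu_length_range[2] < lu_length_range[1])
    lox_error("invalid lu_length_range")
  if (gc <= 0 || gc >= 1) lox_error("gc must be in (0, 1)")
  m <- motif$sequence
  mrc <- revcomp(m)
  with_seed(seed, {
    draw_lu <- function() {
      len <- lu_length_range[1] +
        sample.int(lu_length_range[2] - lu_length_range[1] + 1L, 1L) - 1L
      for (try in 1:100) {
        s <- random_dna(len, gc)
        if (!grepl(m, s, fixed = TRUE) && !grepl(mrc, s, fixed = TRUE))
          return(s)
      }
      lox_error("could not draw a motif-free LU (parameters infeasible)")
    }
    for (attempt in 1:20) {
      lus <- vapply(seq_len(n_lus), function(i) draw_lu(), character(1))
      seqc <- if (topology == "linear") paste(lus, collapse = m)
              else paste0(paste(lus, collapse = m), m)
      n_expected <- if (topology == "linear") n_lus - 1L else n_lus
      if (nrow(scan_motifs(seqc, motif, topology)) == n_expected)
        return(annotate_chromosome(name, seqc, motif, topology))
    }
    lox_error("fixture assembly kept producing chimeric motif occurrences")
  })
}
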