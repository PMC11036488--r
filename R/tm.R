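# Unified nearest-neighbor parameters (Allawi & SantaLucia 1997 / SantaLucia
# 1998). dH in kcal/mol, dS in cal/(mol K), per 5'->3' dinucleotide stack.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# duplex initiation with a terminal G.C / A.T pair, one term per end
INIT_DH <- c(GC = 0.1, AT = 2.3)
INIT_DS <- c(GC = -2.8, AT = 4.1)
GAS_R <- 1.9872  # cal/(mol K)

#' Nearest-neighbor melting temperature of a primer
#'
#' Sums unified nearest-neighbor enthalpy/entropy over all dinucleotide
#' stacks, adds duplex-initiation terms for both terminal base pairs, applies
#' the monovalent-salt entropy correction
#' \eqn{\Delta S' = \Delta S + 0.368 (N-1) \ln[\mathrm{Na}^+]}, and converts
#' via \eqn{T_m = 1000 \Delta H / (\Delta S' + R \ln(C_T/x)) - 273.15} with
#' x = 4 for non-self-complementary primers (x = 1 if the primer is its own
#' reverse complement). Deterministic; increases with GC at fixed length.
#'
#' @param primer DNA string, ACGT only, length >= 8.
#' @param salt_mM monovalent cation concentration (default 50 mM).
#' @param primer_conc_nM total strand concentration (default 250 nM).
#' @return melting temperature in degrees Celsius.
#' @examples
#' melting_temp(strrep("G", 20)) > melting_temp(strrep("A", 20))  # TRUE
#' @export
melting_temp <- function(primer, salt_mM = 50, primer_conc_nM = 250) {
  primer <- check_dna(primer, "primer")
  n <- nchar(primer)
  if (n < 8L) lox_error("primer shorter than 8 nt")
  stacks <- substring(primer, 1:(n - 1), 2:n)
  ends <- substring(primer, c(1L, n), c(1L, n))
  endk <- ifelse(ends %in% c("G", "C"), "GC", "AT")
  dH <- sum(NN_DH[stacks]) + sum(INIT_DH[endk])
  dS <- sum(NN_DS[stacks]) + sum(INIT_DS[endk])
  dS <- dS + 0.368 * (n - 1) * log(salt_mM / 1000)
  ct <- primer_conc_nM * 1e-9
  x <- if (identical(primer, revcomp(primer))) 1 else 4
  1000 * dH / (dS + GAS_R * log(ct / x)) - 273.15
}

#' Mask error-prone regions before primer design
#'
#' Returns the union of (a) homopolymer runs of length >=
#' `homopolymer_min_run`, (b) low-complexity windows whose DUST-style
#' trinucleotide repetitiveness score exceeds `dust_threshold`, (c) any
#' user-supplied BED intervals, and (d) runs of N (always masked). Primers
#' may not overlap masked intervals.
#'
#' The DUST-style score of a window of length w counting trinucleotide t
#' \eqn{c_t} times is \eqn{\sum_t c_t (c_t - 1) / 2 / (w - 3)}; a uniform
#' random sequence scores about 0.5, a perfect repeat scores about w/6.
#'
#' @param sequence DNA string.
#' @param homopolymer_min_run minimum run length masked (default 6).
#' @param dust_threshold score above which a window is masked (default 2).
#' @param dust_window,dust_step window geometry (default 64/32).
#' @param user_bed optional data.frame with `start`/`end` (0-based half-open).
#' @return data.frame of merged masked intervals (`start`, `end`).
#' @export
mask_sequence <- function(sequence, homopolymer_min_run = 6L, dust_threshold = 2,
                          dust_window = 64L, dust_step = 32L, user_bed = NULL) {
  sequence <- check_dna(sequence, "sequence", allow_n = TRUE)
  L <- nchar(sequence)
  iv <- list()
  # homopolymers and N runs
  r <- gregexpr(sprintf("([ACGT])\\1{%d,}|N+", homopolymer_min_run - 1L), sequence)[[1]]
  if (r[1] != -1)
    iv[[length(iv) + 1L]] <- data.frame(start = r - 1L,
                                        end = r - 1L + attr(r, "match.length"))
  # DUST-style low complexity
  if (L >= dust_window) {
    starts <- seq(0L, L - dust_window, by = dust_step)
    for (s in starts) {
      w <- substr(sequence, s + 1L, s + dust_window)
      tri <- substring(w, 1:(dust_window - 2), 3:dust_window)
      ct <- table(tri)
      score <- sum(ct * (ct - 1) / 2) / (dust_window - 3)
      if (score > dust_threshold)
        iv[[length(iv) + 1L]] <- data.frame(start = s, end = s + dust_window)
    }
  }
  if (!is.null(user_bed) && nrow(user_bed)) {
    if (any(user_bed$start < 0) || any(user_bed$end > L))
      lox_error("user mask interval outside sequence bounds")
    iv[[length(iv) + 1L]] <- data.frame(start = user_bed$start, end = user_bed$end)
  }
  merge_intervals(do.call(rbind, iv))
}

merge_intervals <- function(df) {
  if (is.null(df) || nrow(df) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  df <- df[order(df$start, df$end), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  for (i in seq_len(nrow(df))[-1]) {
    j <- nrow(out)
    if (df$start[i] <= out$end[j]) out$end[j] <- max(out$end[j], df$end[i])
    else out <- rbind(out, df[i, ])
  }
  rownames(out) <- NULL
  out[, c("start", "end")]
}

overlaps_any <- function(start, end, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i)
    any(start[i] < intervals$end & end[i] > intervals$start), logical(1))
}
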