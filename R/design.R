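#' Primer design parameters
#'
#' Defaults are standard end-point qPCR ranges: primer 18/20/25 nt,
#' Tm 57/60/63 C, GC 0.30-0.70, amplicon 100-500 bp, off-target screening at
#' up to 4 mismatches, and a fallback that lets an assay span up to 2 motif
#' copies when the neighboring LU is too small to host a primer. All values
#' can be overridden here or via a YAML/JSON config ([read_config()]).
#'
#' @param primer_len length (min, opt, max) in nt.
#' @param tm melting temperature (min, opt, max) in Celsius.
#' @param gc GC-content bounds (min, max), fractions.
#' @param amplicon_len amplicon length bounds (min, max) in bp; the minimum
#'   must exceed the motif length.
#' @param max_offtarget_mismatch Hamming threshold for off-target hits.
#' @param max_span_motifs maximum motif copies one amplicon may span.
#' @param weights penalty weights `w_len`, `w_tm`, `w_gc`, `w_pair`.
#' @param salt_mM,primer_conc_nM conditions for [melting_temp()].
#' @return a `lox_design_params` list.
#' @export
design_params <- function(primer_len = c(18L, 20L, 25L),
                          tm = c(57, 60, 63),
                          gc = c(0.30, 0.70),
                          amplicon_len = c(100L, 500L),
                          max_offtarget_mismatch = 4L,
                          max_span_motifs = 2L,
                          weights = c(w_len = 1, w_tm = 1, w_gc = 1, w_pair = 1),
                          salt_mM = 50, primer_conc_nM = 250) {
  stopifnot(length(primer_len) == 3L, length(tm) == 3L)
  if (is.unsorted(primer_len) || is.unsorted(tm))
    lox_error("primer_len and tm must be (min, opt, max)")
  if (amplicon_len[1] >= amplicon_len[2])
    lox_error("amplicon_len must be (min, max)")
  w <- c(w_len = 1, w_tm = 1, w_gc = 1, w_pair = 1)
  w[names(weights)] <- weights
  structure(list(primer_len = as.integer(primer_len), tm = tm, gc = gc,
                 amplicon_len = as.integer(amplicon_len),
                 max_offtarget_mismatch = as.integer(max_offtarget_mismatch),
                 max_span_motifs = as.integer(max_span_motifs),
                 weights = w, salt_mM = salt_mM, primer_conc_nM = primer_conc_nM),
            class = "lox_design_params")
}

# Precomputed per-position thermodynamic arrays for a (possibly doubled)
# template, so candidate enumeration is O(window) per primer length.
design_context <- function(seq2) {
  r <- charToRaw(seq2)
  code <- integer(length(r))
  code[] <- NA_integer_
  code[r == charToRaw("A")] <- 0L
  code[r == charToRaw("C")] <- 1L
  code[r == charToRaw("G")] <- 2L
  code[r == charToRaw("T")] <- 3L
  isN <- is.na(code)
  n <- length(code)
  # stack p covers bases p, p+1 (0-based)
  dinuc <- 4L * code[-n] + code[-1L] + 1L
  bases <- c("A", "C", "G", "T")
  key <- paste0(rep(bases, each = 4L), rep(bases, 4L))  # key[4a+b+1] = base_a base_b
  dh16 <- NN_DH[key]; ds16 <- NN_DS[key]
  dHv <- dh16[dinuc]; dSv <- ds16[dinuc]
  dHv[is.na(dHv)] <- 0; dSv[is.na(dSv)] <- 0
  gcb <- as.numeric(code %in% c(1L, 2L))
  list(seq2 = seq2,
       csH = c(0, cumsum(dHv)), csS = c(0, cumsum(dSv)),
       csGC = c(0, cumsum(gcb)), csN = c(0, cumsum(as.numeric(isN))),
       end_gc = code %in% c(1L, 2L))
}

# Enumerate all primer candidates within a window [ws, we) (0-based, in the
# unrolled frame of a possibly doubled circular template). Returns
# start/end, primer sequence (reverse-complemented for side "rev"), tm, gc
# and per-primer penalty. Hard Tm/GC/mask constraints applied.
enumerate_primers <- function(ctx, ws, we, side, params, mask2) {
  lens <- params$primer_len[1]:params$primer_len[3]
  ct <- params$primer_conc_nM * 1e-9
  salt_term <- function(len) 0.368 * (len - 1) * log(params$salt_mM / 1000)
  out <- list()
  for (len in lens) {
    if (we - ws < len) next
    starts <- ws:(we - len)
    keep <- (ctx$csN[starts + len + 1L] - ctx$csN[starts + 1L]) == 0
    starts <- starts[keep]
    if (!length(starts)) next
    gcs <- (ctx$csGC[starts + len + 1L] - ctx$csGC[starts + 1L]) / len
    keep <- gcs >= params$gc[1] & gcs <= params$gc[2]
    starts <- starts[keep]; gcs <- gcs[keep]
    if (!length(starts)) next
    masked <- overlaps_any(starts, starts + len, mask2)
    starts <- starts[!masked]; gcs <- gcs[!masked]
    if (!length(starts)) next
    # nearest-neighbor sums via prefix arrays (stacks start .. start+len-2)
    dH <- ctx$csH[starts + len] - ctx$csH[starts + 1L]
    dS <- ctx$csS[starts + len] - ctx$csS[starts + 1L]
    e1 <- ctx$end_gc[starts + 1L]; e2 <- ctx$end_gc[starts + len]
    dH <- dH + ifelse(e1, INIT_DH[["GC"]], INIT_DH[["AT"]]) +
      ifelse(e2, INIT_DH[["GC"]], INIT_DH[["AT"]])
    dS <- dS + ifelse(e1, INIT_DS[["GC"]], INIT_DS[["AT"]]) +
      ifelse(e2, INIT_DS[["GC"]], INIT_DS[["AT"]]) + salt_term(len)
    tms <- 1000 * dH / (dS + GAS_R * log(ct / 4)) - 273.15
    keep <- tms >= params$tm[1] & tms <= params$tm[3]
    starts <- starts[keep]; gcs <- gcs[keep]; tms <- tms[keep]
    if (!length(starts)) next
    w <- params$weights
    pen <- w[["w_len"]] * abs(len - params$primer_len[2]) +
      w[["w_tm"]] * abs(tms - params$tm[2]) +
      w[["w_gc"]] * pmax(0, params$gc[1] - gcs, gcs - params$gc[2])
    seqs <- substring(ctx$seq2, starts + 1L, starts + len)
    if (side == "rev")
      seqs <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
    out[[length(out) + 1L]] <- data.frame(
      start = starts, end = starts + len, seq = seqs,
      tm = tms, gc = gcs, pen = pen, stringsAsFactors = FALSE)
  }
  do.call(rbind, out) %||%
    data.frame(start = integer(0), end = integer(0), seq = character(0),
               tm = numeric(0), gc = numeric(0), pen = numeric(0))
}

# Penalty-minimal (fwd, rev) pair subject to amplicon bounds and template
# non-overlap. Deterministic ties: smaller fwd start, then shorter amplicon,
# then lexicographic fwd_seq, then lexicographic rev_seq.
best_primer_pair <- function(fc, rc, params) {
  if (nrow(fc) == 0L || nrow(rc) == 0L) return(NULL)
  w_pair <- params$weights["w_pair"]
  amp <- params$amplicon_len
  ordf <- order(fc$pen, fc$start, fc$seq)
  fc <- fc[ordf, , drop = FALSE]
  rmin <- min(rc$pen)
  best <- NULL
  for (i in seq_len(nrow(fc))) {
    f <- fc[i, ]
    if (!is.null(best) && f$pen + rmin > best$total) break
    len <- rc$end - f$start
    ok <- len >= amp[1] & len <= amp[2] & rc$start >= f$end
    if (!any(ok)) next
    total <- f$pen + rc$pen[ok] + w_pair * abs(f$tm - rc$tm[ok])
    sub <- which(ok)
    o <- order(total, len[ok], rc$seq[ok])[1]
    cand <- list(total = total[o], fwd = f, rev = rc[sub[o], ],
                 amplicon_len = len[ok][o])
    if (is.null(best) || better_pair(cand, best)) best <- cand
  }
  best
}

better_pair <- function(a, b) {
  if (a$total != b$total) return(a$total < b$total)
  if (a$fwd$start != b$fwd$start) return(a$fwd$start < b$fwd$start)
  if (a$amplicon_len != b$amplicon_len) return(a$amplicon_len < b$amplicon_len)
  if (a$fwd$seq != b$fwd$seq) return(a$fwd$seq < b$fwd$seq)
  a$rev$seq < b$rev$seq
}

empty_pairs_df <- function() {
  data.frame(junction_id = character(0), fwd_seq = character(0),
             rev_seq = character(0), fwd_start = integer(0), fwd_end = integer(0),
             rev_start = integer(0), rev_end = integer(0),
             amplicon_len = integer(0), tm_fwd = numeric(0), tm_rev = numeric(0),
             gc_fwd = numeric(0), gc_rev = numeric(0), spans_motifs = integer(0),
             penalty = numeric(0), offtarget_fwd_hits = integer(0),
             offtarget_rev_hits = integer(0), spurious_amplicon = logical(0),
             status = character(0), stringsAsFactors = FALSE)
}

pair_row <- function(junction_id, best, spans, L = NULL) {
  modL <- function(x) if (is.null(L)) x else x %% L
  data.frame(junction_id = junction_id,
             fwd_seq = best$fwd$seq, rev_seq = best$rev$seq,
             fwd_start = modL(best$fwd$start), fwd_end = modL(best$fwd$end),
             rev_start = modL(best$rev$start), rev_end = modL(best$rev$end),
             amplicon_len = best$amplicon_len,
             tm_fwd = best$fwd$tm, tm_rev = best$rev$tm,
             gc_fwd = best$fwd$gc, gc_rev = best$rev$gc,
             spans_motifs = spans, penalty = best$total,
             offtarget_fwd_hits = NA_integer_, offtarget_rev_hits = NA_integer_,
             spurious_amplicon = NA, status = "ok",
             stringsAsFactors = FALSE)
}

#' Design one diagnostic primer pair per motif junction
#'
#' In `span_motif` mode, for every junction k the forward primer is placed in
#' the upstream LU and the reverse primer in the downstream LU so that the
#' amplicon spans the motif copy between them; loss of that amplicon after
#' SCRaMbLE signals a rearrangement at the junction. If no pair satisfies the
#' constraints (the flanking LU is too short, masked, or Tm/GC-infeasible),
#' the search widens across up to `max_span_motifs` motif copies before the
#' junction is recorded as failed with a machine-readable reason. In
#' `within_unit` mode both primers sit inside a single LU (PCRTag-style
#' assays, which detect deletions only).
#'
#' The returned pair minimizes
#' `w_len*|len-opt| + w_tm*|Tm-opt| + w_gc*dist-to-range` summed over both
#' primers plus `w_pair*|Tm_f - Tm_r|`. The search is exhaustive within the
#' candidate windows and fully deterministic (documented tie-breaks), so
#' identical inputs give byte-identical panels.
#'
#' @param chromosome an annotated `lox_chromosome`.
#' @param params a [design_params()] object.
#' @param masked data.frame of masked intervals ([mask_sequence()]), or NULL.
#' @param mode `"span_motif"` (junction tag) or `"within_unit"` (PCRTag-style).
#' @return a `lox_panel`: `pairs` data.frame (one row per junction, columns
#'   as in the CSV interface, 0-based half-open coordinates) and `failed`
#'   data.frame with reasons in {no_fwd_window, no_rev_window,
#'   no_pair_in_amplicon_range, masked_out}.
#' @export
design_tags <- function(chromosome, params = design_params(), masked = NULL,
                        mode = c("span_motif", "within_unit")) {
  mode <- match.arg(mode)
  chr <- chromosome
  L <- nchar(chr$sequence)
  if (params$amplicon_len[1] <= chr$motif$length)
    lox_error("amplicon minimum must exceed the motif length")
  if (L < params$amplicon_len[1])
    lox_error("chromosome shorter than the minimum amplicon")
  masked <- masked %||% data.frame(start = integer(0), end = integer(0))
  circular <- chr$topology == "circular"
  seq2 <- if (circular) paste0(chr$sequence, chr$sequence) else chr$sequence
  ctx <- design_context(seq2)
  mask2 <- if (circular && nrow(masked))
    rbind(masked, data.frame(start = masked$start + L, end = masked$end + L))
  else masked
  n_lus <- nrow(chr$lus)
  pairs <- list()
  failed <- list()
  fail <- function(id, reason)
    data.frame(junction_id = id, reason = reason, stringsAsFactors = FALSE)

  if (mode == "within_unit") {
    for (i in seq_len(n_lus)) {
      lu <- chr$lus[i, ]
      id <- lu$id
      if (lu$zero_length || lu$length < 2L * params$primer_len[1]) {
        failed[[length(failed) + 1L]] <- fail(id, "no_fwd_window")
        next
      }
      ws <- lu$start
      we <- if (lu$end >= lu$start) lu$end else lu$end + L  # wrapping circular LU
      fc <- enumerate_primers(ctx, ws, we, "fwd", params, mask2)
      rc <- enumerate_primers(ctx, ws, we, "rev", params, mask2)
      best <- best_primer_pair(fc, rc, params)
      if (is.null(best)) {
        reason <- if (nrow(fc) == 0L) if (we - ws < params$primer_len[1]) "no_fwd_window" else "masked_out"
        else if (nrow(rc) == 0L) "no_rev_window"
        else "no_pair_in_amplicon_range"
        failed[[length(failed) + 1L]] <- fail(id, reason)
      } else {
        pairs[[length(pairs) + 1L]] <- pair_row(id, best, 0L, if (circular) L else NULL)
      }
    }
  } else {
    n_j <- nrow(chr$motif_sites)
    if (n_j == 0L) lox_error("chromosome has no motif junction")
    for (k in seq_len(n_j) - 1L) {
      id <- sprintf("[%d:%d]", k, (k + 1L) %% if (circular) n_lus else n_lus)
      found <- NULL
      had_fwd <- FALSE; had_rev <- FALSE; windowless_f <- TRUE; windowless_r <- TRUE
      for (s in 1:params$max_span_motifs) {
        cand_best <- NULL
        for (aoff in 0:(s - 1L)) {
          boff <- s - 1L - aoff
          # host LUs: LU (k - aoff) upstream, LU (k + 1 + boff) downstream
          li <- k - aoff
          ri <- k + 1L + boff
          if (!circular && (li < 0L || ri > n_lus - 1L)) next
          li <- li %% n_lus; ri <- ri %% n_lus
          lu_l <- chr$lus[li + 1L, ]
          lu_r <- chr$lus[ri + 1L, ]
          if (lu_l$zero_length || lu_r$zero_length) next
          # unrolled frame anchored at the left LU start
          fs <- lu_l$start
          fe <- fs + lu_l$length
          m_first_start <- fe                  # first spanned motif begins at left LU end
          rs <- m_first_start
          for (q in 1:s) rs <- rs + chr$motif$length +
            (if (q < s) chr$lus[((li + q) %% n_lus) + 1L, "length"] else 0L)
          re <- rs + lu_r$length
          # amplicon cap trims both windows
          fs <- max(fs, rs + params$primer_len[1] - params$amplicon_len[2])
          re <- min(re, fe - params$primer_len[1] + params$amplicon_len[2])
          if (fe - fs >= params$primer_len[1]) windowless_f <- FALSE
          if (re - rs >= params$primer_len[1]) windowless_r <- FALSE
          if (circular && re > 2L * L) next   # cannot unroll past one full turn
          fc <- enumerate_primers(ctx, fs, fe, "fwd", params, mask2)
          rc <- enumerate_primers(ctx, rs, re, "rev", params, mask2)
          had_fwd <- had_fwd || nrow(fc) > 0L
          had_rev <- had_rev || nrow(rc) > 0L
          b <- best_primer_pair(fc, rc, params)
          if (!is.null(b) && (is.null(cand_best) || better_pair(b, cand_best)))
            cand_best <- b
        }
        if (!is.null(cand_best)) { found <- list(best = cand_best, spans = s); break }
      }
      if (is.null(found)) {
        reason <- if (!had_fwd) if (windowless_f) "no_fwd_window" else "masked_out"
        else if (!had_rev) if (windowless_r) "no_rev_window" else "masked_out"
        else "no_pair_in_amplicon_range"
        failed[[length(failed) + 1L]] <- fail(id, reason)
      } else {
        pairs[[length(pairs) + 1L]] <-
          pair_row(id, found$best, found$spans, if (circular) L else NULL)
      }
    }
  }
  structure(list(reference = chr$name, motif = chr$motif$name,
                 pairs = do.call(rbind, pairs) %||% empty_pairs_df(),
                 failed = do.call(rbind, failed) %||%
                   data.frame(junction_id = character(0), reason = character(0))),
            class = "lox_panel")
}

#' @export
print.lox_panel <- function(x, ...) {
  cat(sprintf("<lox_panel> %s on %s: %d pairs, %d failed junctions\n",
              x$motif, x$reference, nrow(x$pairs), nrow(x$failed)))
  invisible(x)
}

#' Exhaustive off-target screen of a primer panel
#'
#' Brute-force scan of every primer against both strands of every reference
#' sequence, counting Hamming matches with at most `max_mismatch`
#' mismatches. A primer with more than one match anywhere (the intended site
#' included) is flagged as a multi-matcher. Additionally, any unintended
#' forward/reverse hit combination in amplifiable orientation within
#' `max_amplicon` is flagged as a spurious amplicon; by default a hit only
#' counts toward spurious amplicons if its 3'-terminal base matches exactly
#' (polymerase extension requirement, set `require_three_prime = FALSE` to
#' disable).
#'
#' @param panel a `lox_panel`.
#' @param references named character vector of genome sequences.
#' @param max_mismatch Hamming threshold (default from panel params: 4).
#' @param max_amplicon spurious-amplicon size cap in bp.
#' @param require_three_prime exact 3' base required for spurious pairing.
#' @return the panel with `offtarget_fwd_hits`, `offtarget_rev_hits` and
#'   `spurious_amplicon` filled in; all hits attached as attribute "hits".
#' @export
offtarget_scan <- function(panel, references, max_mismatch = 4L,
                           max_amplicon = 1000L, require_three_prime = TRUE) {
  if (length(references) == 0L || any(!nzchar(references)))
    lox_error("empty reference")
  if (max_mismatch < 0L) lox_error("max_mismatch must be >= 0")
  references <- vapply(references, toupper, character(1))
  pr <- panel$pairs
  all_hits <- list()
  scan_one <- function(primer) {
    res <- list()
    for (rn in names(references)) {
      refseq <- references[[rn]]
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") primer else revcomp(primer)
        h <- hamming_hits(refseq, pat, max_mismatch)
        if (nrow(h) == 0L) next
        len <- nchar(primer)
        # 3'-terminal base of the primer: rightmost template base on "+",
        # leftmost on "-"
        tpos <- if (strand == "+") h$start + len else h$start + 1L
        tchr <- substring(refseq, tpos, tpos)
        want <- if (strand == "+") substr(pat, len, len) else substr(pat, 1L, 1L)
        res[[length(res) + 1L]] <- data.frame(
          ref = rn, start = h$start, end = h$start + len, strand = strand,
          mismatches = h$mismatches, three_prime_ok = tchr == want,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, res) %||%
      data.frame(ref = character(0), start = integer(0), end = integer(0),
                 strand = character(0), mismatches = integer(0),
                 three_prime_ok = logical(0))
  }
  for (i in seq_len(nrow(pr))) {
    hf <- scan_one(pr$fwd_seq[i])
    hr <- scan_one(pr$rev_seq[i])
    pr$offtarget_fwd_hits[i] <- nrow(hf)
    pr$offtarget_rev_hits[i] <- nrow(hr)
    # spurious amplicons: any plus-strand hit of either primer upstream of a
    # minus-strand hit of either primer, within max_amplicon, excluding the
    # designed amplicon
    hits <- rbind(cbind(hf, role = "fwd"), cbind(hr, role = "rev"))
    plus <- hits[hits$strand == "+", , drop = FALSE]
    minus <- hits[hits$strand == "-", , drop = FALSE]
    if (require_three_prime) {
      plus <- plus[plus$three_prime_ok, , drop = FALSE]
      minus <- minus[minus$three_prime_ok, , drop = FALSE]
    }
    spurious <- FALSE
    for (a in seq_len(nrow(plus))) {
      b <- minus$ref == plus$ref[a] & minus$start >= plus$end[a] &
        (minus$end - plus$start[a]) <= max_amplicon
      if (!any(b)) next
      intended <- plus$role[a] == "fwd" & minus$role[b] == "rev" &
        plus$start[a] == pr$fwd_start[i] & minus$end[b] == pr$rev_end[i] &
        plus$ref[a] == panel$reference & minus$ref[b] == panel$reference
      if (any(!intended)) { spurious <- TRUE; break }
    }
    pr$spurious_amplicon[i] <- spurious
    all_hits[[pr$junction_id[i]]] <- list(fwd = hf, rev = hr)
  }
  panel$pairs <- pr
  attr(panel, "hits") <- all_hits
  panel
}
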