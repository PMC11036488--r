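# Independent oracles: deliberately naive implementations used only to
# validate package results on small inputs.

LOXP <- "ATAACTTCGTATAATGTACATTATACGAAGTTAT"

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# per-position character comparison; circular handled by scanning every
# rotation of the query at offset zero
oracle_primer_sites <- function(query, primer, max_mismatch, topology = "linear") {
  qc <- strsplit(query, "")[[1]]
  m <- nchar(primer)
  L <- length(qc)
  res <- list()
  scan_one <- function(chars, pat_chars, start_label, strand) {
    mm <- sum(chars != pat_chars)
    if (mm <= max_mismatch)
      data.frame(start = start_label, strand = strand, mismatches = mm,
                 stringsAsFactors = FALSE)
  }
  for (strand in c("+", "-")) {
    pc <- strsplit(if (strand == "+") primer else oracle_revcomp(primer), "")[[1]]
    if (topology == "linear") {
      for (i in 0:(L - m)) {
        r <- scan_one(qc[(i + 1):(i + m)], pc, i, strand)
        if (!is.null(r)) res[[length(res) + 1L]] <- r
      }
    } else {
      for (rot in 0:(L - 1)) {
        rc <- c(qc[(rot + 1):L], qc[seq_len(rot)])[1:m]
        r <- scan_one(rc, pc, rot, strand)
        if (!is.null(r)) res[[length(res) + 1L]] <- r
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(start = integer(0), strand = character(0),
                      mismatches = integer(0)))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# naive quadratic amplicon enumeration: every (plus hit, minus hit) pair
oracle_present <- function(query, fwd, rev, max_amplicon, max_mismatch,
                           topology = "linear") {
  fh <- oracle_primer_sites(query, fwd, max_mismatch, topology)
  rh <- oracle_primer_sites(query, rev, max_mismatch, topology)
  L <- nchar(query)
  pairs_ok <- function(plus, plen, minus, mlen) {
    for (i in seq_len(nrow(plus))) for (j in seq_len(nrow(minus))) {
      s1 <- plus$start[i]; s2 <- minus$start[j]
      if (topology == "circular" && s2 < s1 + plen) s2 <- s2 + L
      e2 <- s2 + mlen
      if (s2 >= s1 + plen && (e2 - s1) <= max_amplicon &&
          (topology == "linear" || (e2 - s1) <= L))
        return(TRUE)
    }
    FALSE
  }
  fp <- fh[fh$strand == "+", ]; fm <- fh[fh$strand == "-", ]
  rp <- rh[rh$strand == "+", ]; rm <- rh[rh$strand == "-", ]
  as.integer(pairs_ok(fp, nchar(fwd), rm, nchar(rev)) ||
               pairs_ok(rp, nchar(rev), fm, nchar(fwd)))
}

# exhaustive primer-pair enumeration for one junction of a small linear
# chromosome (span_motif, single-motif span), fully vectorized
oracle_best_pair <- function(chr, k, params, masked = NULL) {
  masked <- masked %||% data.frame(start = integer(0), end = integer(0))
  site <- chr$motif_sites[k + 1L, ]
  lu_l <- chr$lus[k + 1L, ]
  lu_r <- chr$lus[k + 2L, ]
  cands <- function(ws, we, side) {
    out <- list()
    for (len in params$primer_len[1]:params$primer_len[3]) {
      if (we - ws < len) next
      for (s in ws:(we - len)) {
        tmpl <- substr(chr$sequence, s + 1L, s + len)
        if (nrow(masked) && any(s < masked$end & (s + len) > masked$start)) next
        seqp <- if (side == "rev") loxkit::revcomp(tmpl) else tmpl
        gcv <- sum(strsplit(tmpl, "")[[1]] %in% c("G", "C")) / len
        tmv <- loxkit::melting_temp(seqp, params$salt_mM, params$primer_conc_nM)
        if (gcv < params$gc[1] || gcv > params$gc[2]) next
        if (tmv < params$tm[1] || tmv > params$tm[3]) next
        w <- params$weights
        out[[length(out) + 1L]] <- data.frame(
          start = s, end = s + len, seq = seqp, tm = tmv, gc = gcv,
          pen = w[["w_len"]] * abs(len - params$primer_len[2]) +
            w[["w_tm"]] * abs(tmv - params$tm[2]))
      }
    }
    do.call(rbind, out)
  }
  fc <- cands(lu_l$start, site$start, "fwd")
  rc <- cands(site$end, lu_r$end, "rev")
  if (is.null(fc) || is.null(rc)) return(NULL)
  amp <- outer(fc$start, rc$end, function(a, b) b - a)
  tot <- outer(fc$pen, rc$pen, "+") +
    params$weights[["w_pair"]] * abs(outer(fc$tm, rc$tm, "-"))
  ok <- amp >= params$amplicon_len[1] & amp <= params$amplicon_len[2]
  if (!any(ok)) return(NULL)
  tot[!ok] <- Inf
  best <- min(tot)
  w <- which(tot == best, arr.ind = TRUE)
  # tie-break: smaller fwd start, shorter amplicon, lexicographic fwd_seq
  o <- order(fc$start[w[, 1]], amp[w], fc$seq[w[, 1]], rc$seq[w[, 2]])[1]
  list(penalty = best,
       fwd = fc[w[o, 1], ], rev = rc[w[o, 2], ],
       amplicon_len = amp[w[o, 1], w[o, 2]])
}

# brute-force max-min-Hamming candidate selection over all k-subsets;
# returns the best achievable (min pairwise distance, total score) value
oracle_best_subset_value <- function(mat, k) {
  idx <- utils::combn(nrow(mat), k)
  best <- -Inf
  for (c0 in seq_len(ncol(idx))) {
    rows <- idx[, c0]
    d <- min(as.matrix(stats::dist(mat[rows, , drop = FALSE], method = "manhattan"))[
      upper.tri(diag(k))])
    if (d > best) best <- d
  }
  best
}

expect_lox_error <- function(expr) expect_error(expr, class = "lox_error")
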