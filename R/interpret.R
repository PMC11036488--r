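# Junction k of the panel sits between LU k and LU k+1 (mod n for circular
# chromosomes); a presence row is ordered by those junctions.

#' Classify a presence/absence row into candidate SCRaMbLE events
#'
#' Deterministic rules, applied in order to the maximal runs of consecutive
#' missing amplicons (runs wrap on circular chromosomes):
#' \enumerate{
#'   \item a run of length L >= 2 becomes one candidate deletion of the
#'     L - 1 LUs between its flanking junctions;
#'   \item exactly two singleton runs become one explicitly ambiguous
#'     "inversion_or_translocation" candidate for the block between them
#'     (junction-spanning assays cannot separate the two);
#'   \item any remaining singleton run is "indeterminate" (possible assay
#'     failure, small-LU event, or complex-event boundary);
#'   \item an all-present row yields the single candidate "none".
#' }
#' Every report carries the fixed caveat that duplications are structurally
#' undetectable by junction assays. Candidates are ranked by run length,
#' descending. Calls are indicative only and need sequencing verification.
#'
#' @param presence_row named 0/1 vector over reference-ordered junction ids.
#' @param topology `"linear"` or `"circular"`.
#' @param n_junctions expected row length (defaults to the row's length).
#' @return a `lox_call_report`: `candidates` data.frame (`kind_hypothesis`,
#'   `junction_run`, `inferred_lu_span`, `confidence_note`), `n_missing`,
#'   `diversity_score`.
#' @export
classify_pattern <- function(presence_row, topology = c("linear", "circular"),
                             n_junctions = length(presence_row)) {
  topology <- match.arg(topology)
  if (length(presence_row) != n_junctions)
    lox_error("presence row length does not match the panel")
  if (any(!presence_row %in% c(0L, 1L))) lox_error("presence row must be 0/1")
  nj <- length(presence_row)
  ids <- names(presence_row) %||% sprintf("[%d:%d]", 0:(nj - 1), 1:nj)
  dup_note <- "duplications are undetectable by junction assays"
  cands <- list()
  runs <- zero_runs(presence_row, topology == "circular")
  if (nrow(runs) == 0L) {
    cands[[1]] <- data.frame(kind_hypothesis = "none", junction_run = "",
                             inferred_lu_span = "", run_length = 0L,
                             confidence_note = dup_note, stringsAsFactors = FALSE)
  } else {
    singles <- which(runs$length == 1L)
    for (r in which(runs$length >= 2L)) {
      jr <- junction_indices(runs$start[r], runs$length[r], nj)
      cands[[length(cands) + 1L]] <- data.frame(
        kind_hypothesis = "deletion",
        junction_run = paste(ids[jr + 1L], collapse = ","),
        inferred_lu_span = lu_span_label(jr[1] + 1L, runs$length[r] - 1L, nj, topology),
        run_length = runs$length[r],
        confidence_note = sprintf("deletion of the %d LU(s) between flanking junctions; %s",
                                  runs$length[r] - 1L, dup_note),
        stringsAsFactors = FALSE)
    }
    if (length(singles) == 2L) {
      a <- runs$start[singles[1]]; b <- runs$start[singles[2]]
      span <- singleton_pair_span(a, b, nj, topology)
      cands[[length(cands) + 1L]] <- data.frame(
        kind_hypothesis = "inversion_or_translocation",
        junction_run = paste(ids[c(a, b) + 1L], collapse = ","),
        inferred_lu_span = span$label,
        run_length = 1L,
        confidence_note = paste0("block between the two distant missing junctions; ",
                                 span$note, "ambiguous by design; ", dup_note),
        stringsAsFactors = FALSE)
    } else if (length(singles) > 0L) {
      for (r in singles) {
        j <- runs$start[r]
        cands[[length(cands) + 1L]] <- data.frame(
          kind_hypothesis = "indeterminate",
          junction_run = ids[j + 1L],
          inferred_lu_span = "",
          run_length = 1L,
          confidence_note = paste0("possible assay failure, small-LU event, ",
                                   "or complex-event boundary; ", dup_note),
          stringsAsFactors = FALSE)
      }
    }
  }
  cands <- do.call(rbind, cands)
  cands <- cands[order(-cands$run_length), , drop = FALSE]
  rownames(cands) <- NULL
  structure(list(candidates = cands[, setdiff(names(cands), "run_length")],
                 n_missing = sum(presence_row == 0L),
                 diversity_score = sum(presence_row == 0L)),
            class = "lox_call_report")
}

# maximal runs of zeros; wrapping run merged for circular rows
zero_runs <- function(row, circular) {
  r <- rle(as.integer(row))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  z <- r$values == 0L
  runs <- data.frame(start = starts[z], length = r$lengths[z])
  if (circular && nrow(runs) >= 2L) {
    n <- length(row)
    first <- 1L; last <- nrow(runs)
    if (runs$start[first] == 0L && runs$start[last] + runs$length[last] == n) {
      runs$start[last] <- runs$start[last]
      runs$length[last] <- runs$length[last] + runs$length[first]
      runs <- runs[-first, , drop = FALSE]
    }
  }
  runs
}

junction_indices <- function(start, len, nj) (start + 0:(len - 1L)) %% nj

lu_span_label <- function(first_lu, n_lus, nj, topology) {
  n_units <- if (topology == "circular") nj else nj + 1L
  lus <- (first_lu + 0:(n_lus - 1L)) %% n_units
  paste(paste0("LU", lus), collapse = ",")
}

singleton_pair_span <- function(a, b, nj, topology) {
  if (topology == "linear") {
    lo <- min(a, b); hi <- max(a, b)
    list(label = lu_span_label(lo + 1L, hi - lo, nj, topology), note = "")
  } else {
    # two arcs; hypothesize the shorter, note the complement
    lo <- min(a, b); hi <- max(a, b)
    arc1 <- hi - lo            # LUs lo+1..hi
    arc2 <- nj - arc1          # the complement
    if (arc1 <= arc2)
      list(label = lu_span_label(lo + 1L, arc1, nj, topology),
           note = sprintf("shorter arc reported; complement (%d LUs) is the alternative; ", arc2))
    else
      list(label = lu_span_label(hi + 1L, arc2, nj, topology),
           note = sprintf("shorter arc reported; complement (%d LUs) is the alternative; ", arc1))
  }
}

#' Annotate an observed signed LU arrangement against the reference
#'
#' A deterministic greedy annotator (not a minimal rearrangement-distance
#' solver): the observed arrangement is decomposed into maximal blocks whose
#' internal adjacencies are reference-consistent; missing reference-
#' consecutive LUs become deletions; reference-consecutive runs present in
#' extra copies become duplications (complex); an order-reversed,
#' sign-flipped block sitting between its original reference neighbors is an
#' inversion; blocks that fall outside the longest reference-ordered chain
#' are translocations (complex). `breakpoints` counts observed adjacencies
#' absent from the signed reference adjacency set.
#'
#' @param reference annotated `lox_chromosome` (or character vector of LU ids
#'   in reference order).
#' @param observed a `lox_arrangement`.
#' @return a `lox_comparison`: `counts` (deletions, inversions, complex),
#'   `events` data.frame, `breakpoints`.
#' @export
compare_arrangements <- function(reference, observed) {
  ref_ids <- if (inherits(reference, "lox_chromosome")) reference$lus$id else reference
  n <- length(ref_ids)
  u <- observed$units
  idx <- match(u$lu_id, ref_ids) - 1L
  if (anyNA(idx)) lox_error("observed arrangement contains unknown LU ids")
  sgn <- u$orientation
  circular <- observed$topology == "circular"
  m <- length(idx)

  pair_ok <- function(ia, sa, ib, sb)
    (sa == 1L && sb == 1L && !is.na(succ(ia, n, circular)) && ib == succ(ia, n, circular)) ||
    (sa == -1L && sb == -1L && !is.na(succ(ib, n, circular)) && ia == succ(ib, n, circular))
  consistent_at <- function(a, b) pair_ok(idx[a], sgn[a], idx[b], sgn[b])

  breakpoints <- if (m > 1L)
    sum(vapply(1:(m - 1L), function(a) !consistent_at(a, a + 1L), logical(1)))
  else 0L
  if (circular && m > 1L && !consistent_at(m, 1L))
    breakpoints <- breakpoints + 1L

  events <- list()
  add_event <- function(kind, lus, detail = "")
    events[[length(events) + 1L]] <<- data.frame(
      kind = kind, lus = paste(ref_ids[sort(lus) + 1L], collapse = ","),
      detail = detail, stringsAsFactors = FALSE)

  # deletions: maximal reference-consecutive runs absent from the multiset
  present <- tabulate(idx + 1L, nbins = n)
  missing <- which(present == 0L) - 1L
  if (length(missing)) {
    runs <- split(missing, cumsum(c(1L, diff(missing) != 1L)))
    for (r in runs) add_event("deletion", r)
  }

  # duplications: maximal reference-consecutive runs with copy number >= 2
  dup <- which(present >= 2L) - 1L
  if (length(dup)) {
    runs <- split(dup, cumsum(c(1L, diff(dup) != 1L)))
    for (r in runs) add_event("duplication", r, "complex")
  }

  # Remove extra copies before positional analysis: for each duplicated LU
  # keep the occurrence whose observed neighbors are most reference-
  # consistent (ties: the first), so the remaining arrangement reflects the
  # non-duplication structure.
  drop <- integer(0)
  for (d in dup) {
    occ <- which(idx == d)
    score <- vapply(occ, function(p) {
      s <- 0L
      if (p > 1L && consistent_at(p - 1L, p)) s <- s + 1L
      if (p < m && consistent_at(p, p + 1L)) s <- s + 1L
      s
    }, integer(1))
    keep1 <- occ[order(-score, occ)][1]
    drop <- c(drop, setdiff(occ, keep1))
  }
  if (length(drop)) { idx <- idx[-drop]; sgn <- sgn[-drop]; m <- length(idx) }

  # block decomposition at non-reference-consistent adjacencies
  if (m > 1L) {
    cut <- vapply(1:(m - 1L), function(a)
      !pair_ok(idx[a], sgn[a], idx[a + 1L], sgn[a + 1L]), logical(1))
    block_id <- cumsum(c(1L, cut))
  } else block_id <- 1L
  blocks <- lapply(unname(split(seq_len(m), block_id)), function(pos) {
    list(pos = pos, idx = idx[pos], sgn = sgn[pos],
         inverted = all(sgn[pos] == -1L),
         lo = min(idx[pos]), hi = max(idx[pos]))
  })
  nb <- length(blocks)

  # heaviest reference-ordered chain of blocks; everything outside the chain
  # is out of place
  keep <- chain_blocks(blocks, seq_len(nb))
  for (bi in seq_len(nb)) {
    b <- blocks[[bi]]
    if (b$inverted) {
      if (inversion_in_place(b, blocks, bi, n, circular)) {
        add_event("inversion", b$idx)
      } else {
        add_event("translocation", b$idx, "complex (inverted, out of place)")
      }
    } else if (!(bi %in% keep)) {
      add_event("translocation", b$idx, "complex")
    }
  }

  events <- do.call(rbind, events) %||%
    data.frame(kind = character(0), lus = character(0), detail = character(0))
  counts <- c(deletions = sum(events$kind == "deletion"),
              inversions = sum(events$kind == "inversion"),
              complex = sum(events$kind %in% c("duplication", "translocation")))
  structure(list(sample = observed$source, counts = counts, events = events,
                 breakpoints = breakpoints),
            class = "lox_comparison")
}

succ <- function(i, n, circular) if (circular) (i + 1L) %% n else i + 1L

# longest (max total LU count) increasing chain of blocks by reference
# interval order; returns block indices kept
chain_blocks <- function(blocks, cand) {
  k <- length(cand)
  if (k == 0L) return(integer(0))
  wt <- vapply(cand, function(i) length(blocks[[i]]$idx), integer(1))
  lo <- vapply(cand, function(i) blocks[[i]]$lo, integer(1))
  hi <- vapply(cand, function(i) blocks[[i]]$hi, integer(1))
  best <- wt
  prev <- rep(0L, k)
  for (a in seq_len(k)) for (b in seq_len(a - 1L)) {
    if (hi[b] < lo[a] && best[b] + wt[a] > best[a]) {
      best[a] <- best[b] + wt[a]
      prev[a] <- b
    }
  }
  a <- which.max(best)
  out <- integer(0)
  while (a != 0L) { out <- c(cand[a], out); a <- prev[a] }
  out
}

# an inverted block is an inversion (not a transposed inversion) if its
# observed neighbors are its reference neighbors
inversion_in_place <- function(b, blocks, bi, n, circular) {
  left_ok <- TRUE; right_ok <- TRUE
  if (bi > 1L) {
    nb <- blocks[[bi - 1L]]
    left_ok <- !nb$inverted && succ(nb$idx[length(nb$idx)], n, circular) == b$lo
  }
  if (bi < length(blocks)) {
    nb <- blocks[[bi + 1L]]
    right_ok <- !nb$inverted && succ(b$hi, n, circular) == nb$idx[1L]
  }
  left_ok && right_ok
}

#' Diversity score of a presence row
#'
#' The number of missing amplicons — a proxy for how extensively an isolate
#' has been rearranged.
#'
#' @param presence_row 0/1 vector.
#' @return integer.
#' @export
diversity_score <- function(presence_row) sum(presence_row == 0L)

#' Select diverse candidate isolates from a genotype matrix
#'
#' Greedy max-min design: seed with the highest-scoring sample (ties broken
#' lexicographically by name), then repeatedly add the sample maximizing the
#' minimum Hamming distance to the chosen set (ties: higher diversity score,
#' then name). Picks with min-distance 0 to the chosen set duplicate an
#' already-selected genotype and carry a redundancy warning. The aim is the
#' paper-style triage: avoid sequencing identical candidates, prefer diverse
#' highly SCRaMbLEd ones.
#'
#' @param matrix genotype matrix (samples x junctions).
#' @param k number of candidates to select (1..n_samples).
#' @return data.frame `sample`, `diversity_score`, `min_distance`,
#'   `redundant`, in pick order.
#' @export
select_candidates <- function(matrix, k) {
  if (k <= 0L) lox_error("k must be positive")
  if (k > nrow(matrix)) lox_error("k exceeds the number of samples")
  scores <- apply(matrix, 1L, diversity_score)
  nm <- rownames(matrix)
  chosen <- character(0)
  out <- list()
  seed <- nm[order(-scores, nm)][1]
  chosen <- seed
  out[[1]] <- data.frame(sample = seed, diversity_score = scores[[seed]],
                         min_distance = NA_integer_, redundant = FALSE)
  while (length(chosen) < k) {
    rest <- setdiff(nm, chosen)
    mind <- vapply(rest, function(s)
      min(vapply(chosen, function(c0) sum(matrix[s, ] != matrix[c0, ]), integer(1))),
      integer(1))
    pick <- rest[order(-mind, -scores[rest], rest)][1]
    out[[length(out) + 1L]] <- data.frame(
      sample = pick, diversity_score = scores[[pick]],
      min_distance = mind[[pick]], redundant = mind[[pick]] == 0L)
    if (mind[[pick]] == 0L)
      warning(sprintf("candidate %s is identical to an already-selected genotype", pick))
    chosen <- c(chosen, pick)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-check pattern calls against simulator truth logs
#'
#' Tallies, per sample, how many true events the pattern classifier
#' recovered. Documented blind spots — duplications, and events confined to
#' junctions without tags — are excluded from the denominator and counted
#' separately. Deletions count as recovered when a deletion candidate's
#' inferred span contains every deleted LU; inversions/translocations count
#' as recovered-with-ambiguity when an inversion_or_translocation candidate
#' overlaps the event's LUs.
#'
#' @param truth named list: per sample, a list of event records with `kind`
#'   and `lu_ids` (ids involved at event time).
#' @param reports named list of `lox_call_report` for the same samples.
#' @return data.frame per sample: `true_positive`, `ambiguous_recovered`,
#'   `false_negative`, `blind_spot`, `false_positive_candidates`.
#' @export
insilico_crosscheck <- function(truth, reports) {
  if (!setequal(names(truth), names(reports)))
    lox_error("sample name mismatch between truth logs and reports")
  rows <- lapply(names(truth), function(s) {
    evs <- truth[[s]]
    rep <- reports[[s]]
    cand <- rep$candidates
    cand_lus <- strsplit(cand$inferred_lu_span, ",", fixed = TRUE)
    tp <- amb <- fn <- blind <- 0L
    matched <- rep(FALSE, nrow(cand))
    for (ev in evs) {
      if (ev$kind == "duplication") { blind <- blind + 1L; next }
      lus <- ev$lu_ids
      if (ev$kind == "deletion") {
        hit <- which(cand$kind_hypothesis == "deletion" &
                       vapply(cand_lus, function(x) all(lus %in% x), logical(1)))
        if (length(hit)) { tp <- tp + 1L; matched[hit[1]] <- TRUE }
        else fn <- fn + 1L
      } else {
        hit <- which(cand$kind_hypothesis == "inversion_or_translocation" &
                       vapply(cand_lus, function(x) any(lus %in% x), logical(1)))
        if (length(hit)) { amb <- amb + 1L; matched[hit[1]] <- TRUE }
        else fn <- fn + 1L
      }
    }
    fp <- sum(!matched & !cand$kind_hypothesis %in% c("none", "indeterminate"))
    data.frame(sample = s, true_positive = tp, ambiguous_recovered = amb,
               false_negative = fn, blind_spot = blind,
               false_positive_candidates = fp, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
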