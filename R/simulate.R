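#' Construct a recombination event
#'
#' Events operate on whole LUs (Cre recombination between motif copies);
#' `lu_span` indexes a contiguous block of the *current* arrangement
#' (0-based, inclusive). `target_pos` is the insertion index into the
#' remaining (translocation) or full (duplication) arrangement.
#'
#' @param kind one of `"deletion"`, `"inversion"`, `"duplication"`,
#'   `"translocation"`.
#' @param lu_span integer 2-vector `(i, j)`, 0-based inclusive block bounds.
#' @param target_pos insertion index (duplication/translocation only);
#'   duplication defaults to tandem (`j + 1`).
#' @param target_orientation +1 or -1 for the inserted copy/block.
#' @return a `lox_event` list.
#' @export
recombination_event <- function(kind = c("deletion", "inversion", "duplication",
                                         "translocation"),
                                lu_span, target_pos = NULL,
                                target_orientation = 1L) {
  kind <- match.arg(kind)
  lu_span <- as.integer(lu_span)
  if (length(lu_span) != 2L || lu_span[1] > lu_span[2] || lu_span[1] < 0L)
    lox_error("invalid lu_span")
  structure(list(kind = kind, lu_span = lu_span,
                 target_pos = if (!is.null(target_pos)) as.integer(target_pos),
                 target_orientation = as.integer(target_orientation)),
            class = "lox_event")
}

#' Apply one recombination event to an arrangement
#'
#' Deletion removes the block; inversion reverses block order and flips every
#' orientation sign (an involution); duplication inserts a copy of the block
#' at `target_pos` (default tandem, same orientation); translocation removes
#' the block and reinserts it at `target_pos` in the remaining arrangement.
#' Motif-count bookkeeping follows [render_arrangement()] arithmetic:
#' deleting b LUs removes b motif copies, inversion preserves them,
#' duplicating b LUs adds b.
#'
#' @param arrangement a `lox_arrangement`.
#' @param event a [recombination_event()].
#' @param protected_lus character vector of LU ids that may never be deleted.
#' @return the rearranged `lox_arrangement`.
#' @export
apply_event <- function(arrangement, event, protected_lus = character(0)) {
  u <- arrangement$units
  n <- nrow(u)
  i <- event$lu_span[1]; j <- event$lu_span[2]
  if (j >= n) lox_error("lu_span out of range")
  idx <- (i:j) + 1L
  block <- u[idx, , drop = FALSE]
  if (event$kind == "deletion") {
    if (any(block$lu_id %in% protected_lus))
      lox_error("viability error: deletion would remove a protected LU")
    if (length(idx) == n)
      lox_error("viability error: deletion would empty the arrangement")
    u <- u[-idx, , drop = FALSE]
  } else if (event$kind == "inversion") {
    inv <- block[rev(seq_len(nrow(block))), , drop = FALSE]
    inv$orientation <- -inv$orientation
    u[idx, ] <- inv
  } else if (event$kind == "duplication") {
    t <- event$target_pos %||% (j + 1L)
    if (t < 0L || t > n) lox_error("target_pos out of range")
    copy <- block
    if (event$target_orientation < 0L) {
      copy <- copy[rev(seq_len(nrow(copy))), , drop = FALSE]
      copy$orientation <- -copy$orientation
    }
    u <- rbind(u[seq_len(t), , drop = FALSE], copy,
               u[seq_len(n - t) + t, , drop = FALSE])
  } else {  # translocation
    t <- event$target_pos
    if (is.null(t)) lox_error("translocation requires target_pos")
    if (t >= i && t <= j) lox_error("target_pos inside the moved block")
    rest <- u[-idx, , drop = FALSE]
    # convert target (index in the original arrangement) to the remaining frame
    tr <- if (t > j) t - nrow(block) else t
    if (tr < 0L || tr > nrow(rest)) lox_error("target_pos out of range")
    mv <- block
    if (event$target_orientation < 0L) {
      mv <- mv[rev(seq_len(nrow(mv))), , drop = FALSE]
      mv$orientation <- -mv$orientation
    }
    u <- rbind(rest[seq_len(tr), , drop = FALSE], mv,
               rest[seq_len(nrow(rest) - tr) + tr, , drop = FALSE])
  }
  rownames(u) <- NULL
  arrangement$units <- u
  arrangement
}

#' Simulation configuration
#'
#' The default event mix follows the observed proportions on the circular
#' synthetic chromosome — deletions 63%, inversions 23%, the remaining 14%
#' split evenly between duplications and translocations. Event counts per
#' isolate are Poisson(lambda = 3) by default; block lengths are geometric
#' with mean 2 LUs, truncated to the current arrangement.
#'
#' @param event_mix named probabilities over the four event kinds (sums to 1).
#' @param n_events either `list(fixed = k)` or `list(poisson = lambda)`.
#' @param block_mean mean block length in LUs (geometric).
#' @param protected_lus LU ids that must survive (e.g., a centromere LU).
#' @param seed master seed.
#' @param max_retries rejected-event redraw budget per event.
#' @return a `lox_sim_config` list.
#' @export
sim_config <- function(event_mix = c(deletion = 0.63, inversion = 0.23,
                                     duplication = 0.07, translocation = 0.07),
                       n_events = list(poisson = 3),
                       block_mean = 2, protected_lus = character(0),
                       seed = 1L, max_retries = 100L) {
  if (abs(sum(event_mix) - 1) > 1e-8) lox_error("event_mix must sum to 1")
  kinds <- c("deletion", "inversion", "duplication", "translocation")
  if (!all(names(event_mix) %in% kinds)) lox_error("unknown event kind in mix")
  mix <- stats::setNames(numeric(4), kinds)
  mix[names(event_mix)] <- event_mix
  structure(list(event_mix = mix, n_events = n_events, block_mean = block_mean,
                 protected_lus = protected_lus, seed = as.integer(seed),
                 max_retries = as.integer(max_retries)),
            class = "lox_sim_config")
}

draw_n_events <- function(n_events) {
  if (!is.null(n_events$fixed)) as.integer(n_events$fixed)
  else if (!is.null(n_events$poisson)) rpois(1L, n_events$poisson)
  else lox_error("n_events must specify fixed or poisson")
}

#' Sample a random SCRaMbLE event history
#'
#' Draws the number of events, then for each event draws a kind from the
#' mix, a contiguous block (start uniform over valid positions, length
#' geometric with mean `block_mean`, truncated), and insertion targets where
#' applicable. Events that would violate viability (protected-LU deletion,
#' emptying the arrangement) or be no-ops (translocation back to the same
#' slot with + orientation) are rejected and redrawn within the retry
#' budget. Fully reproducible from `config$seed`; the returned log replays
#' to the final arrangement via [apply_event()].
#'
#' @param arrangement starting `lox_arrangement`.
#' @param config a [sim_config()].
#' @return list with `arrangement` (final) and `log` (list of `lox_event`).
#' @export
sample_events <- function(arrangement, config) {
  with_seed(config$seed, {
    n <- draw_n_events(config$n_events)
    log <- list()
    cur <- arrangement
    for (e in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(config$max_retries)) {
        len_cur <- nrow(cur$units)
        kind <- sample(names(config$event_mix), 1L, prob = config$event_mix)
        b <- min(1L + rgeom(1L, 1 / config$block_mean), len_cur)
        if (kind == "deletion" && b >= len_cur) b <- len_cur - 1L
        if (b < 1L) next
        i <- sample.int(len_cur - b + 1L, 1L) - 1L
        j <- i + b - 1L
        ev <- switch(kind,
          deletion = recombination_event("deletion", c(i, j)),
          inversion = recombination_event("inversion", c(i, j)),
          duplication = {
            t <- sample.int(len_cur + 1L, 1L) - 1L
            ori <- sample(c(1L, -1L), 1L, prob = c(0.8, 0.2))
            recombination_event("duplication", c(i, j), t, ori)
          },
          translocation = {
            choices <- setdiff(0:(len_cur - b), i)  # i would be a no-op slot
            if (length(choices) == 0L) next
            tr <- if (length(choices) == 1L) choices else sample(choices, 1L)
            t <- if (tr > i) tr + b else tr   # express in pre-removal frame
            ori <- sample(c(1L, -1L), 1L, prob = c(0.8, 0.2))
            recombination_event("translocation", c(i, j), t, ori)
          })
        nxt <- tryCatch(apply_event(cur, ev, config$protected_lus),
                        lox_error = function(err) NULL)
        if (!is.null(nxt)) {
          cur <- nxt
          log[[length(log) + 1L]] <- ev
          ok <- TRUE
          break
        }
      }
      if (!ok)
        lox_error(sprintf(
          "simulation error: retry budget exhausted at event %d (protected LUs: %s)",
          e, paste(config$protected_lus, collapse = ",")))
    }
    list(arrangement = cur, log = log)
  })
}

#' Simulate a SCRaMbLEd population with truth logs
#'
#' Applies an independent random event history to each isolate, rendering
#' each final arrangement to sequence. Per-isolate RNG substreams are
#' derived from the master seed (`(seed + 1000003 * index) mod (2^31 - 1)`),
#' so any isolate can be regenerated in isolation and logs are portable.
#'
#' @param reference annotated `lox_chromosome`.
#' @param n_isolates number of isolates (>= 1).
#' @param config a [sim_config()]; its `seed` is the master seed.
#' @param fasta,truth_json optional output paths (population FASTA; one JSON
#'   truth log with per-isolate ordered event lists).
#' @return a `lox_population`: list with `isolates` (named list of
#'   `arrangement`, `log`, `sequence`), `reference` name and `topology`.
#' @export
simulate_population <- function(reference, n_isolates, config,
                                fasta = NULL, truth_json = NULL) {
  if (n_isolates < 1L) lox_error("n_isolates must be >= 1")
  start <- identity_arrangement(reference)
  isolates <- list()
  for (i in seq_len(n_isolates)) {
    sub <- config
    sub$seed <- as.integer((config$seed + 1000003 * i) %% (2^31 - 1))
    res <- sample_events(start, sub)
    res$sequence <- render_arrangement(res$arrangement, reference)
    isolates[[sprintf("iso%04d", i)]] <- res
  }
  pop <- structure(list(isolates = isolates, reference = reference$name,
                        topology = reference$topology),
                   class = "lox_population")
  if (!is.null(fasta))
    write_fasta(vapply(isolates, `[[`, character(1), "sequence"), fasta)
  if (!is.null(truth_json)) write_truth_logs(pop, truth_json)
  pop
}

#' Write / read population truth logs as JSON
#'
#' One record per isolate: the ordered event list (kind, lu_span, lu_ids
#' involved at the time of the event, target_pos, target_orientation) and
#' the final signed LU arrangement.
#'
#' @param population a `lox_population`.
#' @param path JSON file.
#' @export
write_truth_logs <- function(population, path) {
  recs <- lapply(population$isolates, function(iso) {
    list(events = lapply(iso$log, function(ev)
      list(kind = ev$kind, lu_span = ev$lu_span,
           target_pos = ev$target_pos, target_orientation = ev$target_orientation)),
      final_units = iso$arrangement$units)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_truth_logs
#' @return `read_truth_logs`: named list of per-isolate records.
#' @export
read_truth_logs <- function(path) {
  if (!file.exists(path)) lox_io_error(sprintf("input file not found: %s", path))
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}

#' Replay a truth log
#' @param reference annotated reference chromosome.
#' @param log list of `lox_event` (or parsed JSON event records).
#' @return the final `lox_arrangement`.
#' @export
replay_log <- function(reference, log) {
  cur <- identity_arrangement(reference)
  for (ev in log) {
    if (!inherits(ev, "lox_event")) {
      tp <- ev$target_pos
      if (!is.null(tp) && length(tp) == 1L && is.na(tp)) tp <- NULL
      ori <- ev$target_orientation %||% 1L
      if (length(ori) == 1L && is.na(ori)) ori <- 1L
      ev <- recombination_event(ev$kind, unlist(ev$lu_span), tp, ori)
    }
    cur <- apply_event(cur, ev)
  }
  cur
}
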