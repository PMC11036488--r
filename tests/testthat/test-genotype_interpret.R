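row_with_zeros <- function(n, zeros) {
  r <- rep(1L, n)
  r[zeros + 1L] <- 0L
  names(r) <- sprintf("[%d:%d]", 0:(n - 1), 1:n)
  r
}

test_that("classify_pattern implements the published signatures", {
  # two consecutive missing junctions [1:2],[2:3] -> deletion of LU2
  rep1 <- classify_pattern(row_with_zeros(8, c(1, 2)))
  expect_equal(rep1$candidates$kind_hypothesis, "deletion")
  expect_equal(rep1$candidates$inferred_lu_span, "LU2")
  expect_equal(rep1$n_missing, 2L)
  # all present -> "none" with the duplication caveat
  rep2 <- classify_pattern(row_with_zeros(8, integer(0)))
  expect_equal(rep2$candidates$kind_hypothesis, "none")
  expect_match(rep2$candidates$confidence_note, "duplications are undetectable")
  # two distant singletons [1:2] and [6:7] -> one ambiguous candidate, LUs 2-6
  rep3 <- classify_pattern(row_with_zeros(8, c(1, 6)))
  expect_equal(rep3$candidates$kind_hypothesis, "inversion_or_translocation")
  expect_equal(rep3$candidates$inferred_lu_span,
               paste(paste0("LU", 2:6), collapse = ","))
  # lone singleton -> indeterminate
  rep4 <- classify_pattern(row_with_zeros(8, 3))
  expect_equal(rep4$candidates$kind_hypothesis, "indeterminate")
  # long run + singleton: deletion reported first (ranked by run length),
  # singleton stays indeterminate (not paired)
  rep5 <- classify_pattern(row_with_zeros(10, c(2, 3, 4, 8)))
  expect_equal(rep5$candidates$kind_hypothesis[1], "deletion")
  expect_true("indeterminate" %in% rep5$candidates$kind_hypothesis)
  # classify_pattern never hypothesizes a duplication
  for (r in list(rep1, rep2, rep3, rep4, rep5))
    expect_false(any(grepl("duplication", r$candidates$kind_hypothesis)))
  expect_lox_error(classify_pattern(c(1L, 0L), n_junctions = 5L))
  expect_lox_error(classify_pattern(c(1L, 2L)))
})

test_that("classify_pattern wraps runs on circular chromosomes", {
  # zeros at the last and first junction form one wrapped run of 2
  r <- row_with_zeros(8, c(0, 7))
  rep <- classify_pattern(r, "circular")
  expect_equal(rep$candidates$kind_hypothesis, "deletion")
  expect_equal(rep$candidates$inferred_lu_span, "LU0")
  # two distant singletons on a circle: shorter arc hypothesized
  rep2 <- classify_pattern(row_with_zeros(12, c(1, 9)), "circular")
  expect_equal(rep2$candidates$kind_hypothesis, "inversion_or_translocation")
  expect_equal(rep2$candidates$inferred_lu_span, "LU10,LU11,LU0,LU1")
  expect_match(rep2$candidates$confidence_note, "complement")
})

test_that("compare_arrangements annotates the constructed single events", {
  ref <- c("A", "B", "C", "D")
  obs <- function(ids, ori = 1L) lu_arrangement(ids, ori)
  inv <- compare_arrangements(ref, obs(c("A", "C", "B", "D"),
                                       c(1L, -1L, -1L, 1L)))
  expect_equal(unname(inv$counts), c(0L, 1L, 0L))
  expect_equal(inv$events$lus, "B,C")
  expect_equal(inv$breakpoints, 2L)
  del <- compare_arrangements(ref, obs(c("A", "C", "D")))
  expect_equal(unname(del$counts), c(1L, 0L, 0L))
  expect_equal(del$events$lus[del$events$kind == "deletion"], "B")
  dup <- compare_arrangements(ref, obs(c("A", "B", "B", "C", "D")))
  expect_equal(unname(dup$counts), c(0L, 0L, 1L))
  expect_equal(dup$events$kind, "duplication")
  tr <- compare_arrangements(ref, obs(c("A", "C", "D", "B")))
  expect_equal(unname(tr$counts), c(0L, 0L, 1L))
  expect_equal(tr$events$kind, "translocation")
  expect_equal(tr$events$lus, "B")
  expect_lox_error(compare_arrangements(ref, obs(c("A", "Z"))))
})

test_that("compare_arrangements recovers kind and span for all single events", {
  chr <- std_fixture()
  ids <- chr$lus$id
  n <- length(ids)
  arr0 <- identity_arrangement(chr)
  set.seed(99)
  for (kind in c("deletion", "inversion", "duplication", "translocation")) {
    for (i in 0:(n - 2)) {
      for (s in 1:3) {
        b <- sample(1:3, 1)
        j <- min(i + b - 1L, n - 1L)
        ev <- switch(kind,
          deletion = recombination_event("deletion", c(i, j)),
          inversion = recombination_event("inversion", c(i, j)),
          duplication = recombination_event("duplication", c(i, j)),
          translocation = {
            ch <- setdiff(0:(n - (j - i + 1L)), i)
            tr <- if (length(ch) == 1L) ch else sample(ch, 1)
            t <- if (tr > i) tr + (j - i + 1L) else tr
            recombination_event("translocation", c(i, j), t)
          })
        cmp <- compare_arrangements(chr, apply_event(arr0, ev))
        want <- paste(ids[(i:j) + 1L], collapse = ",")
        lab <- paste(kind, i, j, s)
        if (kind == "deletion") {
          expect_equal(unname(cmp$counts), c(1L, 0L, 0L), info = lab)
          expect_equal(cmp$events$lus, want, info = lab)
        } else if (kind == "inversion") {
          expect_equal(unname(cmp$counts), c(0L, 1L, 0L), info = lab)
          expect_equal(cmp$events$lus, want, info = lab)
        } else if (kind == "duplication") {
          expect_equal(unname(cmp$counts), c(0L, 0L, 1L), info = lab)
          expect_equal(cmp$events$lus[1], want, info = lab)
          expect_equal(cmp$events$kind[1], kind, info = lab)
        } else {
          # a transposition has two sequence-identical annotations: the moved
          # block, or the complementary block it jumped over
          t <- ev$target_pos
          comp <- if (t > j) ((j + 1L):(t - 1L)) else (t:(i - 1L))
          want2 <- paste(ids[comp + 1L], collapse = ",")
          expect_equal(unname(cmp$counts), c(0L, 0L, 1L), info = lab)
          expect_equal(cmp$events$kind[1], "translocation", info = lab)
          expect_true(cmp$events$lus[1] %in% c(want, want2), info = lab)
        }
      }
    }
  }
})

test_that("deletions equal the reference-minus-observed multiset difference", {
  chr <- std_fixture()
  cfg <- sim_config(n_events = list(fixed = 3), seed = 55L)
  for (i in 1:10) {
    cfg$seed <- 550L + i
    res <- sample_events(identity_arrangement(chr), cfg)
    cmp <- compare_arrangements(chr, res$arrangement)
    reported <- unlist(strsplit(cmp$events$lus[cmp$events$kind == "deletion"], ","))
    missing <- setdiff(chr$lus$id, res$arrangement$units$lu_id)
    expect_setequal(reported %||% character(0), missing)
  }
})

test_that("diversity scoring and max-min candidate selection", {
  rows <- rbind(
    s1 = c(1, 1, 1, 1, 1, 1),
    s2 = c(0, 0, 1, 1, 1, 1),
    s3 = c(0, 0, 1, 1, 1, 1),
    s4 = c(1, 1, 0, 0, 0, 1),
    s5 = c(0, 1, 0, 1, 0, 0),
    s6 = c(1, 0, 1, 0, 1, 0))
  storage.mode(rows) <- "integer"
  expect_equal(diversity_score(rows["s4", ]), 3L)
  one <- select_candidates(rows, 1L)
  expect_equal(one$sample, "s5")  # max score 4, ties broken by name
  expect_lox_error(select_candidates(rows, 0L))
  expect_lox_error(select_candidates(rows, 99L))
  # identical rows: second pick flagged redundant when forced
  two <- suppressWarnings(select_candidates(rows[c("s2", "s3"), ], 2L))
  expect_true(two$redundant[2])
  expect_equal(two$min_distance[2], 0L)
  # k = 3 matches exhaustive max-min search on the min-distance value
  sel <- select_candidates(rows, 3L)
  got <- min(as.matrix(stats::dist(rows[sel$sample, ], method = "manhattan"))[
    upper.tri(diag(3))])
  expect_equal(got, oracle_best_subset_value(rows, 3L))
})

test_that("insilico_crosscheck tallies recoveries and blind spots", {
  chr <- std_fixture()
  panel <- std_panel()
  nj <- nrow(panel$pairs)
  mk_report <- function(zeros) classify_pattern(row_with_zeros(nj, zeros))
  # deletions recovered
  truth <- list(isoA = list(list(kind = "deletion", lu_ids = "LU5")),
                isoB = list(list(kind = "duplication", lu_ids = "LU3")),
                isoC = list(list(kind = "inversion", lu_ids = c("LU4", "LU5"))))
  reports <- list(isoA = mk_report(c(4, 5)), isoB = mk_report(integer(0)),
                  isoC = mk_report(c(3, 5)))
  cc <- insilico_crosscheck(truth, reports)
  expect_equal(cc$true_positive[cc$sample == "isoA"], 1L)
  expect_equal(cc$blind_spot[cc$sample == "isoB"], 1L)
  expect_equal(cc$false_negative[cc$sample == "isoB"], 0L)
  expect_equal(cc$ambiguous_recovered[cc$sample == "isoC"], 1L)
  expect_lox_error(insilico_crosscheck(truth, reports[c("isoA", "isoB")]))
})
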