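test_that("melting_temp matches hand-computed nearest-neighbor sum", {
  # frozen oracle: manual dH/dS summation over unified NN stacks for this
  # 20-mer (dH = -154.5 kcal/mol, salt-corrected dS = -438.0462 cal/mol/K,
  # 50 mM Na+, 250 nM strand)
  expect_equal(melting_temp("AGCGTACCGTTAGACCTGAA"), 54.8685, tolerance = 1e-4)
  expect_gt(melting_temp(strrep("G", 20)), melting_temp(strrep("A", 20)))
  # monotone in length for a repeated motif, and in GC at fixed length
  tms <- vapply(c(12, 16, 20, 24), function(n)
    melting_temp(strrep("AGGT", n / 4)), numeric(1))
  expect_true(all(diff(tms) > 0))
  expect_lox_error(melting_temp("ACG"))
  expect_lox_error(melting_temp("ACGTACGTNN"))
})

test_that("masking: homopolymers, user BED, bounds", {
  s <- paste0(with_seed_chr(1, 100), strrep("A", 10), with_seed_chr(2, 100))
  m <- mask_sequence(s)
  expect_true(any(m$start <= 100 & m$end >= 110))
  clean <- "ACGGTCAGTCAGGCATCAGTAGCATGCATGCAGTCAGTTGACA"
  expect_equal(nrow(mask_sequence(clean)), 0L)
  m2 <- mask_sequence(clean, user_bed = data.frame(start = 5L, end = 15L))
  expect_equal(m2, data.frame(start = 5L, end = 15L))
  expect_lox_error(mask_sequence(clean, user_bed = data.frame(start = 0L, end = 999L)))
  # low-complexity repeat masked by the DUST-style rule
  rep_seq <- paste0(with_seed_chr(3, 80), strrep("CAG", 40), with_seed_chr(4, 80))
  m3 <- mask_sequence(rep_seq)
  expect_true(any(m3$start < 200 & m3$end > 100))
})

test_that("design_tags returns the penalty-minimal pair (oracle equivalence)", {
  chr <- small_fixture()
  params <- design_params()
  panel <- design_tags(chr, params)
  expect_equal(nrow(panel$pairs), 2L)
  expect_equal(panel$pairs$spans_motifs, c(1L, 1L))
  for (k in 0:1) {
    row <- panel$pairs[k + 1L, ]
    best <- oracle_best_pair(chr, k, params)
    expect_equal(row$penalty, best$penalty, tolerance = 1e-9)
    expect_identical(row$fwd_seq, best$fwd$seq)
    expect_identical(row$rev_seq, best$rev$seq)
    expect_equal(row$amplicon_len, best$amplicon_len)
    # amplicon contains exactly one motif copy
    amp <- substr(chr$sequence, row$fwd_start + 1L, row$rev_end)
    expect_equal(nrow(scan_motifs(amp, chr$motif)), 1L)
  }
})

test_that("returned pairs satisfy all hard constraints independently", {
  chr <- std_fixture()
  params <- design_params()
  panel <- std_panel()
  expect_equal(nrow(panel$pairs), 11L)
  for (i in seq_len(nrow(panel$pairs))) {
    p <- panel$pairs[i, ]
    expect_true(nchar(p$fwd_seq) %in% params$primer_len[1]:params$primer_len[3])
    expect_true(nchar(p$rev_seq) %in% params$primer_len[1]:params$primer_len[3])
    for (tmv in c(p$tm_fwd, p$tm_rev))
      expect_true(tmv >= params$tm[1] && tmv <= params$tm[3])
    for (gcv in c(p$gc_fwd, p$gc_rev))
      expect_true(gcv >= params$gc[1] && gcv <= params$gc[2])
    expect_true(p$amplicon_len >= params$amplicon_len[1] &&
                  p$amplicon_len <= params$amplicon_len[2])
    expect_equal(p$amplicon_len, p$rev_end - p$fwd_start)
    # rev_seq is the reverse complement of the template at rev_interval
    expect_identical(p$rev_seq,
                     revcomp(substr(chr$sequence, p$rev_start + 1L, p$rev_end)))
    # Tm/GC recomputed independently
    expect_equal(p$tm_fwd, melting_temp(p$fwd_seq), tolerance = 1e-6)
    expect_equal(p$gc_rev, gcf <- {
      b <- strsplit(p$rev_seq, "")[[1]]; sum(b %in% c("G", "C")) / length(b)
    }, tolerance = 1e-12)
  }
  # determinism: identical inputs, byte-identical panels
  expect_identical(panel$pairs, design_tags(chr, params)$pairs)
})

test_that("small middle LU triggers the two-motif spanning fallback", {
  chr <- tiny_mid_fixture()
  expect_equal(chr$lus$length[2], 12L)
  panel <- design_tags(chr, design_params())
  expect_equal(nrow(panel$pairs), 2L)
  expect_equal(panel$pairs$spans_motifs, c(2L, 2L))
  for (i in 1:2) {
    p <- panel$pairs[i, ]
    amp <- substr(chr$sequence, p$fwd_start + 1L, p$rev_end)
    expect_equal(nrow(scan_motifs(amp, chr$motif)), 2L)
  }
  # with the fallback disabled, both junctions fail with a reason
  p1 <- design_params(max_span_motifs = 1L)
  panel1 <- design_tags(chr, p1)
  expect_equal(nrow(panel1$pairs), 0L)
  expect_setequal(panel1$failed$reason,
                  c("no_rev_window", "no_fwd_window"))
})

test_that("within_unit mode keeps both primers inside one LU", {
  chr <- small_fixture()
  panel <- design_tags(chr, design_params(), mode = "within_unit")
  expect_equal(nrow(panel$pairs), 3L)
  expect_true(all(panel$pairs$spans_motifs == 0L))
  for (i in seq_len(nrow(panel$pairs))) {
    p <- panel$pairs[i, ]
    lu <- chr$lus[chr$lus$id == p$junction_id, ]
    expect_true(p$fwd_start >= lu$start && p$rev_end <= lu$end)
    amp <- substr(chr$sequence, p$fwd_start + 1L, p$rev_end)
    expect_equal(nrow(scan_motifs(amp, chr$motif)), 0L)
  }
})

test_that("masked junction regions push design away or fail it", {
  chr <- small_fixture()
  # mask the entire right flank of junction 0 (all of LU1) at span 1; the
  # design must widen to span 2 or fail with masked_out
  masked <- data.frame(start = chr$lus$start[2], end = chr$lus$end[2])
  panel <- design_tags(chr, design_params(), masked = masked)
  r0 <- panel$pairs[panel$pairs$junction_id == "[0:1]", ]
  if (nrow(r0)) {
    expect_equal(r0$spans_motifs, 2L)
  } else {
    expect_true("masked_out" %in% panel$failed$reason)
  }
})

test_that("off-target screen flags planted duplicates and spurious pairs", {
  chr <- small_fixture()
  panel <- design_tags(chr, design_params())
  p <- panel$pairs[1, ]
  refs <- c(small = chr$sequence)
  scanned <- offtarget_scan(panel, refs, max_mismatch = 0L)
  expect_equal(scanned$pairs$offtarget_fwd_hits[1], 1L)
  expect_false(scanned$pairs$spurious_amplicon[1])
  # plant a second verbatim copy of the fwd primer elsewhere
  decoy <- paste0(with_seed_chr(21, 300), p$fwd_seq, with_seed_chr(22, 300))
  s2 <- offtarget_scan(panel, c(refs, decoy = decoy), max_mismatch = 0L)
  expect_equal(s2$pairs$offtarget_fwd_hits[1], 2L)
  # a stray fwd + rev-orientation site 300 bp apart on another contig
  spur <- paste0(with_seed_chr(23, 50), p$fwd_seq, with_seed_chr(24, 300),
                 revcomp(p$rev_seq), with_seed_chr(25, 50))
  s3 <- offtarget_scan(panel, c(refs, contig2 = spur), max_mismatch = 0L)
  expect_true(s3$pairs$spurious_amplicon[1])
  # mismatch threshold: a site at Hamming distance 5 is invisible at max 4
  fwd5 <- p$fwd_seq
  sub <- c(A = "C", C = "A", G = "T", T = "G")
  pos <- c(2L, 5L, 8L, 11L, 14L)
  for (q in pos) substr(fwd5, q, q) <- sub[[substr(fwd5, q, q)]]
  far <- paste0(with_seed_chr(26, 100), fwd5, with_seed_chr(27, 100))
  s4 <- offtarget_scan(panel, c(refs, far = far), max_mismatch = 4L)
  expect_equal(s4$pairs$offtarget_fwd_hits[1], 1L)
  expect_lox_error(offtarget_scan(panel, character(0)))
})

test_that("panel CSV round-trips through the package reader", {
  panel <- design_tags(small_fixture(), design_params())
  csv <- tempfile(fileext = ".csv")
  write_panel(panel, csv)
  back <- read_panel(csv)
  expect_equal(back$pairs$junction_id, panel$pairs$junction_id)
  expect_equal(back$pairs$fwd_seq, panel$pairs$fwd_seq)
  expect_equal(back$pairs$penalty, panel$pairs$penalty, tolerance = 1e-9)
})
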