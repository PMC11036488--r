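# Shared fixtures, built once per test run. The "standard" fixture follows
# the acceptance geometry: 12 LUs of 1.5-2.5 kb, so no amplicon at the
# 1000 bp cap can bridge a whole LU.

.fx_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fx_cache)) assign(key, build(), envir = .fx_cache)
  get(key, envir = .fx_cache)
}

std_fixture <- function() memo("std", function()
  generate_fixture(n_lus = 12, lu_length_range = c(1500, 2500), seed = 42,
                   name = "std"))

std_panel <- function() memo("std_panel", function()
  design_tags(std_fixture(), design_params()))

small_fixture <- function() memo("small", function()
  generate_fixture(n_lus = 3, lu_length_range = c(600, 600), seed = 11,
                   name = "small"))

# a chromosome with a middle LU too small to host any primer (12 bp, below
# the minimum primer length), forcing the two-motif spanning fallback
tiny_mid_fixture <- function() memo("tiny_mid", function() {
  base <- generate_fixture(n_lus = 2, lu_length_range = c(600, 600), seed = 5)
  mid <- with_seed_chr(7, 12)
  seqc <- paste(c(base$lus$sequence[1], mid, base$lus$sequence[2]),
                collapse = base$motif$sequence)
  annotate_chromosome("tiny_mid", seqc, base$motif, "linear")
})

# deterministic random DNA without touching the global RNG
with_seed_chr <- function(seed, n, gc = 0.4) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
}

delete_lu <- function(chr, lu_index) {
  ids <- chr$lus$id[chr$lus$index != lu_index]
  lu_arrangement(ids, 1L, chr$topology, chr$name)
}
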