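# loxkit

Genotyping toolkit for SCRaMbLEd synthetic chromosomes.

## The problem

Synthetic Sc2.0 yeast chromosomes carry a 34 bp palindromic Cre recombination
site, **loxPsym** (`ATAACTTCGTATAATGTACATTATACGAAGTTAT`), downstream of most
nonessential genes. Inducing Cre (**SCRaMbLE**) recombines pairs of loxPsym
copies and thereby stochastically deletes, inverts, duplicates and
translocates the chromosome segments between them — the **loxP units (LUs)**.
A single isogenic strain becomes a highly diverse population, and the
bottleneck shifts to triage: which isolates are worth long-read sequencing?

A cheap answer is end-point qPCR with **junction-spanning primer pairs**: one
diagnostic amplicon across each loxPsym junction. If junction *k* between
LU*k* and LU*k*+1 is intact, the assay amplifies; if a rearrangement moved or
removed either flank, the amplicon is lost. The resulting 0/1 vector over
junctions is a rearrangement fingerprint: a run of ≥ 2 consecutive missing
amplicons suggests a deletion of the LUs between its flanking junctions; two
distant lone missing amplicons suggest a large inversion or translocation
(the two cannot be separated by presence/absence alone); duplications are
structurally invisible. loxkit implements the dry-lab side of this workflow
end to end:

| module | what it does |
|---|---|
| genome model | motif scanning, LU segmentation, signed LU arrangements, sequence rendering, synthetic fixtures |
| tag design | one penalty-minimal junction-spanning primer pair per junction (nearest-neighbor Tm, GC, masking, small-LU fallback), exhaustive off-target screen |
| in-silico PCR | mismatch-tolerant amplicon prediction (≤ 1000 bp, ≤ 2 mismatches per primer by default) and binary genotype matrices |
| SCRaMbLE simulator | event sampling (default mix: 63% deletion, 23% inversion, 7% duplication, 7% translocation), populations with replayable truth logs |
| interpretation | pattern classification of presence rows, event annotation of signed arrangements, diversity-driven candidate selection |

Primer pairs are scored by
`w_len·|len−opt| + w_tm·|Tm−opt| + w_gc·dist(gc, range)` per primer plus
`w_pair·|Tm_f − Tm_r|`, minimized exhaustively within the junction windows.
Melting temperatures use the unified nearest-neighbor model
(ΔH/ΔS stack sums, monovalent-salt entropy correction,
`Tm = 1000·ΔH / (ΔS′ + R·ln(C_T/4)) − 273.15`).

All genomic coordinates, in memory and on disk (BED/CSV), are **0-based
half-open**.

## Worked example

```r
library(loxkit)

chr <- generate_fixture(n_lus = 6, lu_length_range = c(1500, 2000),
                        seed = 7, name = "demo")
chr
#> <lox_chromosome> demo: 10904 bp, linear, 5 x loxPsym, 6 LUs

panel <- design_tags(chr, design_params())
panel$pairs[1:3, c("junction_id", "fwd_seq", "rev_seq", "amplicon_len",
                   "tm_fwd", "tm_rev", "penalty")]
#>   junction_id              fwd_seq              rev_seq amplicon_len tm_fwd tm_rev penalty
#> 1       [0:1] CGGCATGGGTTGTCCCTGAG CGAGGGACCGTAAGGGTCCA          405  59.54  59.46   1.071
#> 2       [1:2] TTCCAGTGGTGGTCGGTGGT TTCGCTGGGCTACGGCTAGT          279  59.82  59.82   0.368
#> 3       [2:3] TGGAGGGGAGAATGGCTGCA GTGTACTGCTGCTGCCTGCT          457  59.67  59.48   1.045

cfg <- sim_config(n_events = list(fixed = 1), seed = 99)
pop <- simulate_population(chr, 3, cfg)
m <- genotype(vapply(pop$isolates, `[[`, character(1), "sequence"), panel)
m
#>         [0:1] [1:2] [2:3] [3:4] [4:5]
#> iso0001     0     0     1     1     1
#> iso0002     1     1     0     1     0
#> iso0003     1     1     0     0     0

classify_pattern(m["iso0002", ])$candidates[, 1:3]
#>              kind_hypothesis junction_run inferred_lu_span
#> 1 inversion_or_translocation  [2:3],[4:5]          LU3,LU4

compare_arrangements(chr, pop$isolates$iso0002$arrangement)$counts
#> deletions inversions    complex
#>         0          1          0
```

iso0002's two distant missing amplicons ([2:3] and [4:5]) are called as an
ambiguous inversion-or-translocation of LU3–LU4; the truth log confirms a
single inversion of exactly that block. iso0001's run of two consecutive
zeros is the deletion signature.

## Command line

Every step is also a subcommand (exit codes: 0 ok, 1 validation, 2 I/O):

```sh
Rscript inst/exec/loxkit fixture --n-lus 12 --seed 7 --out fix.fa --out-bed fix.bed
Rscript inst/exec/loxkit design  --fasta fix.fa --out panel.csv
Rscript inst/exec/loxkit simulate --fasta fix.fa --n 12 --seed 1 --out pop.fa --out-json pop.json
Rscript inst/exec/loxkit insilico --fasta pop.fa --panel panel.csv --out geno.tsv
Rscript inst/exec/loxkit classify --matrix geno.tsv --out calls.json
Rscript inst/exec/loxkit select   --matrix geno.tsv --k 4 --out picks.tsv
```

`scan` runs a motif census on any FASTA (e.g., a real synIII sequence);
`offtarget` screens a panel CSV against a genome; `compare` annotates truth
logs against the reference. A `--config file.yaml` supplies defaults that
flags override; a run manifest is written next to the outputs.

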