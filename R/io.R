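# File formats. All genomic coordinates on disk are 0-based half-open,
# matching BED; this is stated in every writer's docs.

#' Read a FASTA file as named uppercase character sequences
#'
#' Identifiers must be unique; description text after the first whitespace is
#' dropped. Lowercase (softmasked) bases are uppercased.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) lox_io_error(sprintf("input file not found: %s", path))
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) lox_error("duplicate FASTA identifiers")
  stats::setNames(toupper(as.character(ss)), nm)
}

#' Write named sequences to FASTA (wrapped at 60 columns)
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read a BED file of mask/feature intervals
#'
#' Minimal 3+ column BED: chrom, start, end (0-based half-open), optional
#' name. Malformed lines raise an error naming the line number.
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) lox_io_error(sprintf("input file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  out <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L || is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3]))))
      lox_error(sprintf("malformed BED line %d in %s", i, path))
    data.frame(chrom = f[1], start = as.integer(f[2]), end = as.integer(f[3]),
               name = if (length(f) >= 4L) f[4] else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out) %||% data.frame(chrom = character(0), start = integer(0),
                                      end = integer(0), name = character(0))
}

#' Write intervals as BED (0-based half-open)
#' @param intervals data.frame with `start`, `end` and optionally `name`.
#' @param chrom chromosome name for all rows.
#' @param path output file.
#' @export
write_bed <- function(intervals, chrom, path) {
  df <- data.frame(chrom = chrom, start = intervals$start, end = intervals$end,
                   name = intervals$name %||% ".")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write motif sites and LU intervals of a chromosome as BED
#' @param chromosome a `lox_chromosome`.
#' @param path output file; motif rows are named "motif<k>", LU rows "LU<k>".
#' @export
write_annotation_bed <- function(chromosome, path) {
  ms <- chromosome$motif_sites
  ms$name <- paste0("motif", seq_len(nrow(ms)) - 1L)
  lu <- chromosome$lus[, c("start", "end")]
  lu$name <- chromosome$lus$id
  df <- rbind(ms[, c("start", "end", "name")], lu)
  write_bed(df, chromosome$name, path)
}

#' Write a primer panel to CSV
#'
#' One row per junction; coordinates 0-based half-open. This is the dialect
#' consumed back by [read_panel()] and by the in-silico PCR engine.
#'
#' @param panel a `lox_panel` from [design_tags()].
#' @param path output CSV.
#' @export
write_panel <- function(panel, path) {
  write.csv(panel$pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a primer panel CSV
#' @param path CSV written by [write_panel()] (or any file with at least
#'   `junction_id`, `fwd_seq`, `rev_seq` columns).
#' @return a `lox_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) lox_io_error(sprintf("input file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("junction_id", "fwd_seq", "rev_seq")
  if (!all(need %in% names(df)))
    lox_error(sprintf("panel CSV must contain columns: %s", paste(need, collapse = ", ")))
  structure(list(reference = attr(df, "reference") %||% NA_character_,
                 motif = NA_character_, pairs = df,
                 failed = data.frame(junction_id = character(0), reason = character(0))),
            class = "lox_panel")
}

#' Write / read a genotype matrix as TSV
#'
#' Rows are samples, columns are junction ids in reference panel order,
#' cells 0/1.
#' @param mat integer matrix with dimnames.
#' @param path output TSV.
#' @export
write_genotype_matrix <- function(mat, path) {
  df <- data.frame(sample = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @return `read_genotype_matrix`: the matrix.
#' @export
read_genotype_matrix <- function(path) {
  if (!file.exists(path)) lox_io_error(sprintf("input file not found: %s", path))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read a run configuration (YAML or JSON)
#'
#' Tool parameters mirror the defaults of [design_params()], [sim_config()]
#' and the in-silico PCR settings; any subset may be given and is merged over
#' the defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) lox_io_error(sprintf("input file not found: %s", path))
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Render the genotype matrix as a two-color heatmap image
#'
#' Samples as rows, junctions as reference-ordered columns; presence dark,
#' absence light (colors configurable).
#'
#' @param mat genotype matrix.
#' @param path output image (png).
#' @param colors length-2 vector: absent, present.
#' @export
write_genotype_heatmap <- function(mat, path, colors = c("white", "grey25")) {
  tryCatch({
    pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE,
                       color = colors, breaks = c(-0.5, 0.5, 1.5),
                       legend = FALSE, border_color = "grey80",
                       filename = path, silent = TRUE)
    invisible(path)
  }, error = function(e) {
    warning("heatmap rendering unavailable: ", conditionMessage(e))
    invisible(NULL)
  })
}
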