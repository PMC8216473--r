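#' Read genomic intervals from a BED file
#'
#' Parses BED3/BED6/BED12 lines into a tibble of 0-based half-open intervals.
#' `track`, `browser` and `#` comment lines are skipped. Every interval is
#' validated: integer coordinates with `0 <= start < end`; violations raise a
#' parse error naming the offending line.
#'
#' @param path Path to a tab-separated BED file.
#' @param min_fields Minimum number of fields each record must have
#'   (default 3). With 6 or more fields, `name`, `score` and `strand` are
#'   kept.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`. Input order is preserved.
#' @export
read_bed <- function(path, min_fields = 3) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_fields)) {
    i <- which(nf < min_fields)[1]
    abort(sprintf("BED parse error at line %d: %d field(s), expected >= %d",
                  lineno[i], nf[i], min_fields))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start < 0 | start >= end
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "BED parse error at line %d: invalid interval (start=%s, end=%s)",
      lineno[i], vapply(fields, `[`, "", 2L)[i], vapply(fields, `[`, "", 3L)[i]))
  }
  out <- tibble(chrom = vapply(fields, `[`, "", 1L), start = start, end = end)
  if (all(nf >= 4)) out$name <- vapply(fields, `[`, "", 4L)
  if (all(nf >= 5)) out$score <- suppressWarnings(
    as.numeric(vapply(fields, `[`, "", 5L)))
  if (all(nf >= 6)) {
    strand <- vapply(fields, `[`, "", 6L)
    if (any(!strand %in% c("+", "-", "."))) {
      i <- which(!strand %in% c("+", "-", "."))[1]
      abort(sprintf("BED parse error at line %d: bad strand '%s'",
                    lineno[i], strand[i]))
    }
    out$strand <- strand
  }
  out
}

#' Write intervals to a BED file
#'
#' Inverse of [read_bed()]: writes `chrom`, `start`, `end` and, when present,
#' `name`, `score`, `strand` as tab-separated BED.
#'
#' @param x A tibble of intervals.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # pad optional columns so BED field order is respected
  df <- as.data.frame(x[, cols, drop = FALSE])
  if ("strand" %in% cols) {
    if (!"name" %in% cols) df$name <- "."
    if (!"score" %in% cols) df$score <- 0
    df <- df[, c("chrom", "start", "end", "name", "score", "strand")]
  } else if ("score" %in% cols && !"name" %in% cols) {
    df$name <- "."
    df <- df[, c("chrom", "start", "end", "name", "score")]
  }
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a plain FASTA file.
#' @param alphabet `"DNA"` (default) or `"RNA"`. RNA reading normalizes any
#'   `T` to `U`, so miRBase-style DNA-alphabet miRNA files are accepted.
#' @return A tibble with columns `id` and `sequence`. Duplicate ids are an
#'   error.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) abort("duplicate sequence ids in FASTA")
  seqs <- toupper(as.character(ss))
  if (alphabet == "RNA") seqs <- gsub("T", "U", seqs, fixed = TRUE)
  if (any(!nzchar(seqs))) abort("empty sequence in FASTA")
  tibble(id = ids, sequence = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param x Tibble with `id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  writeLines(paste0(">", x$id, "\n", x$sequence), path)
  invisible(path)
}

#' Extract the sequence of a genomic interval
#'
#' Returns the plus-strand substring for `strand == "+"` and its reverse
#' complement for `strand == "-"`. Coordinates are 0-based half-open.
#'
#' @param genome Named character vector (or tibble from [read_fasta()]) of
#'   chromosome sequences.
#' @param iv A one-row data frame (or list) with `chrom`, `start`, `end` and
#'   optionally `strand`.
#' @param as_rna If `TRUE`, return the RNA alphabet (T read as U).
#' @return A single string.
#' @export
extract_sequence <- function(genome, iv, as_rna = FALSE) {
  if (is.data.frame(genome)) genome <- setNames(genome$sequence, genome$id)
  chrom <- as.character(iv$chrom)
  if (!chrom %in% names(genome)) abort(paste0("unknown chrom: ", chrom))
  start <- as.integer(iv$start); end <- as.integer(iv$end)
  len <- nchar(genome[[chrom]])
  if (start < 0 || end > len || start >= end)
    abort(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                  start, end, chrom, len))
  s <- substr(genome[[chrom]], start + 1L, end)
  strand <- if ("strand" %in% names(iv)) as.character(iv$strand) else "+"
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      gsub("U", "T", s, fixed = TRUE))))
  }
  if (as_rna) s <- gsub("T", "U", s, fixed = TRUE)
  s
}

#' Read a gene-level expression fold-change table
#'
#' Expects a TSV with a header containing `gene_id` and `log2fc` columns.
#' Duplicate `gene_id` rows are collapsed by their arithmetic mean.
#'
#' @param path Path to the TSV.
#' @return A tibble with one row per gene: `gene_id`, `log2fc`.
#' @export
read_expression_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "log2fc") %in% names(df)))
    abort("expression table must have columns gene_id and log2fc")
  if (!is.numeric(df$log2fc)) abort("log2fc column is not numeric")
  if (any(!is.finite(df$log2fc))) abort("log2fc contains non-finite values")
  df |>
    group_by(.data$gene_id) |>
    summarise(log2fc = mean(.data$log2fc), .groups = "drop")
}

# reverse complement of an RNA string (character in, character out)
rna_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
}

# reverse complement of a DNA string
dna_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
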