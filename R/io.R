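# TSV / BED / FASTA input-output. All TSVs use "NA" as the missing-value
# sentinel; genomic coordinates are 0-based half-open throughout.

#' Read a gene x sample matrix from TSV
#'
#' First column = gene ids (must be unique), header = sample ids. Parse
#' errors report the offending id or line.
#'
#' @param path TSV file.
#' @param kind "counts" (checked non-negative integer), "expression", or
#'   "ratios" (NA allowed).
#' @return Named numeric matrix.
#' @export
read_matrix <- function(path, kind = c("counts", "expression", "ratios")) {
  kind <- match.arg(kind)
  df <- readr::read_tsv(path, show_col_types = FALSE, na = "NA")
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    abort(paste0("duplicated gene id(s) in ", path, ": ",
                 paste(unique(dup), collapse = ", ")))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- names(df)[-1][!vapply(df[-1], is.numeric, TRUE)]
    abort(paste0("non-numeric column(s) in ", path, ": ",
                 paste(bad, collapse = ", ")))
  }
  rownames(m) <- ids
  if (kind == "counts") {
    storage.mode(m) <- "double"
    assert_count_matrix(m)
  }
  m
}

#' Write a gene x sample matrix to TSV
#'
#' @param mat matrix with gene rownames and sample colnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  df <- dplyr::bind_cols(tibble(gene_id = rownames(mat)),
                         as_tibble(mat))
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' Requires columns sample_id, individual, species, datatype, batch, sex.
#'
#' @param path TSV file.
#' @return Tibble.
#' @export
read_sample_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  assert_samples(df, required = c("sample_id", "individual", "species",
                                  "datatype", "batch", "sex"))
  df
}

#' Write a result tibble to TSV (NA sentinel "NA")
#'
#' List columns (e.g. expressed_in) are collapsed to comma-separated strings.
#'
#' @param table tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  is_list <- vapply(table, is.list, TRUE)
  for (cl in names(table)[is_list])
    table[[cl]] <- vapply(table[[cl]], paste, "", collapse = ",")
  readr::write_tsv(table, path, na = "NA")
  invisible(path)
}

#' Read a BED file (0-based, half-open)
#'
#' @param path BED file with 3-6 columns.
#' @return Tibble: chrom, start, end and, when present, gene_id (BED name),
#'   score, strand.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  nc <- ncol(df)
  if (nc < 3) abort("BED needs at least 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (nc >= 4) names(df)[4] <- "gene_id"
  if (nc >= 5) names(df)[5] <- "score"
  if (nc >= 6) names(df)[6] <- "strand"
  if (any(df$end < df$start)) abort("BED interval with end < start")
  df
}

#' Write intervals as 6-column BED
#'
#' @param intervals tibble with chrom, start, end, gene_id and optionally
#'   score, strand.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- tibble(chrom = intervals$chrom,
               start = intervals$start,
               end = intervals$end,
               name = intervals$gene_id %||% ".",
               score = intervals$score %||% 0,
               strand = intervals$strand %||% "+")
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read a per-base conservation track from TSV
#'
#' Accepts 2 columns (pos, score; chrom defaults to "chr1") or 3 columns
#' (chrom, pos, score).
#'
#' @param path TSV file without header.
#' @return Tibble: chrom, pos, score.
#' @export
read_conservation <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(df) == 2) {
    names(df) <- c("pos", "score")
    df$chrom <- "chr1"
  } else if (ncol(df) >= 3) {
    df <- df[, 1:3]
    names(df) <- c("chrom", "pos", "score")
  } else abort("conservation track needs 2 or 3 columns")
  if (any(df$score < 0 | df$score > 1))
    abort("conservation scores must lie in [0,1]")
  df[, c("chrom", "pos", "score")]
}

#' Write a simulated multi-omic dataset to a directory of text files
#'
#' Counts, protein ratios, sample table, gene lengths, and truth as TSV.
#'
#' @param sim a [simulate_multiomic()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_multiomic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(sim$rna_counts, file.path(dir, "rna_counts.tsv"))
  write_matrix(sim$rpf_counts, file.path(dir, "rpf_counts.tsv"))
  write_matrix(sim$protein_ratios, file.path(dir, "protein_ratios.tsv"))
  write_results(sim$samples, file.path(dir, "samples.tsv"))
  write_results(sim$gene_lengths, file.path(dir, "gene_lengths.tsv"))
  write_results(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a multi-omic dataset written by [write_multiomic()]
#'
#' @param dir directory containing the TSV files.
#' @return A list of class `multiomic_sim` (without a config element).
#' @export
read_multiomic <- function(dir) {
  out <- list(
    rna_counts = read_matrix(file.path(dir, "rna_counts.tsv"), "counts"),
    rpf_counts = read_matrix(file.path(dir, "rpf_counts.tsv"), "counts"),
    protein_ratios = read_matrix(file.path(dir, "protein_ratios.tsv"),
                                 "ratios"),
    samples = read_sample_table(file.path(dir, "samples.tsv")),
    gene_lengths = readr::read_tsv(file.path(dir, "gene_lengths.tsv"),
                                   show_col_types = FALSE))
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path))
    out$truth <- readr::read_tsv(truth_path, show_col_types = FALSE)
  structure(out, class = "multiomic_sim")
}
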