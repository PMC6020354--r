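# Ribosome-profiling quality metrics: codon-periodicity profile around
# conserved translation initiation sites (TIS), and species-specific
# footprint-mappability lengths from exact k-mer uniqueness.

#' Conserved translation-initiation-site windows
#'
#' Builds fixed-width windows centred on each gene's first CDS base (plus
#' strand only) and retains those whose mean conservation score reaches the
#' cutoff. Windows extending past the covered chromosome bounds are dropped
#' with a warning.
#'
#' @param cds_starts tibble with columns gene_id, chrom, pos (0-based
#'   position of the first CDS base) and optionally strand (rows with strand
#'   other than "+" are ignored).
#' @param cons conservation track: tibble with columns chrom, pos, score
#'   (scores in `[0,1]`).
#' @param window window width in bp (default 100; half upstream, half
#'   downstream of the CDS start, half-open).
#' @param cutoff minimum mean conservation (default 0.9).
#' @return Tibble of class `tis_window_set`: gene_id, chrom, start, end,
#'   frame_anchor (the CDS start), mean_conservation.
#' @export
define_conserved_tis <- function(cds_starts, cons, window = 100,
                                 cutoff = 0.9) {
  if (any(cons$score < 0 | cons$score > 1))
    abort("conservation scores must lie in [0,1]")
  if ("strand" %in% names(cds_starts))
    cds_starts <- cds_starts[cds_starts$strand == "+", , drop = FALSE]
  half <- floor(window / 2)
  out <- vector("list", nrow(cds_starts))
  dropped <- 0L
  for (i in seq_len(nrow(cds_starts))) {
    row <- cds_starts[i, ]
    start <- row$pos - half
    end <- start + window
    track <- cons[cons$chrom == row$chrom, ]
    sc <- track$score[match(start:(end - 1L), track$pos)]
    if (start < 0 || anyNA(sc)) {
      dropped <- dropped + 1L
      next
    }
    out[[i]] <- tibble(gene_id = row$gene_id, chrom = row$chrom,
                       start = as.integer(start), end = as.integer(end),
                       frame_anchor = as.integer(row$pos),
                       mean_conservation = mean(sc))
  }
  if (dropped > 0)
    warn(paste0(dropped, " window(s) extended past the conservation track and were dropped"))
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0)
    res <- tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  frame_anchor = integer(), mean_conservation = numeric())
  res <- res[res$mean_conservation >= cutoff, , drop = FALSE]
  class(res) <- c("tis_window_set", class(res))
  res
}

#' Codon-periodicity profile around initiation sites
#'
#' Aggregates footprint 5'-end positions over all initiation-site windows,
#' normalising by the total number of in-window reads, so the profile is a
#' probability mass over positions relative to the initiation site. Reported
#' coordinates are shifted downstream by `p_site_offset` so the pattern is
#' centred at the ribosomal P site; the shift is display-only and does not
#' change the mass.
#'
#' @param fp footprints: tibble with columns chrom, pos (5'-most base,
#'   0-based) and optionally strand.
#' @param tis a [define_conserved_tis()] window set (non-empty).
#' @param p_site_offset display offset in nt (default 12).
#' @return Tibble of class `periodicity_profile`: position (relative to the
#'   initiation site, after the P-site shift), frame (position mod 3 before
#'   the shift), enrichment. Attribute `n_reads` carries the in-window read
#'   total; with zero in-window reads the profile is all zero and attribute
#'   `empty` is TRUE.
#' @export
periodicity_profile <- function(fp, tis, p_site_offset = 12) {
  if (nrow(tis) == 0) abort("empty TIS window set")
  width <- unique(tis$end - tis$start)
  if (length(width) != 1) abort("all windows must share one width")
  counts <- rep(0, width)  # indexed by offset from window start
  frames <- integer(width)
  total <- 0L
  for (i in seq_len(nrow(tis))) {
    w <- tis[i, ]
    sel <- fp$chrom == w$chrom & fp$pos >= w$start & fp$pos < w$end
    if (!any(sel)) next
    rel <- fp$pos[sel] - w$start
    tb <- tabulate(rel + 1L, nbins = width)
    counts <- counts + tb
    total <- total + sum(tb)
  }
  anchor_off <- tis$frame_anchor[1] - tis$start[1]
  rel_pos <- seq_len(width) - 1L - anchor_off
  out <- tibble(position = rel_pos + p_site_offset,
                frame = ((rel_pos %% 3L) + 3L) %% 3L,
                enrichment = if (total > 0) counts / total else counts)
  attr(out, "n_reads") <- total
  attr(out, "empty") <- total == 0
  class(out) <- c("periodicity_profile", class(out))
  out
}

# count occurrences of every k-mer of `genome` on both strands
kmer_occurrences <- function(genome, k) {
  all_kmers <- unlist(lapply(as.character(genome), function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  tab <- table(all_kmers)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(names(tab))))
  occ <- as.integer(tab) + ifelse(rc %in% names(tab),
                                  as.integer(tab[rc]), 0L)
  setNames(occ, names(tab))
}

#' Species-specific mappable gene lengths from k-mer uniqueness
#'
#' For each gene, counts the exonic footprint start positions whose k-mer
#' (taken within the exon, never junction-spanning) occurs exactly once in
#' the genome counting both strands. This emulates tiling synthetic
#' footprints of the median footprint length across all orthologous exons and
#' retaining uniquely mapping positions; uniqueness here is exact k-mer
#' identity.
#'
#' @param genome a [Biostrings::DNAStringSet] (or path to a FASTA file).
#' @param exons tibble with columns chrom, start, end (0-based half-open),
#'   gene_id.
#' @param k footprint length (default 29, the median footprint length).
#' @return Tibble: gene_id, length (total exonic bp), mappable_length.
#' @export
mappable_lengths <- function(genome, exons, k = 29) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (k < 1) abort("`k` must be >= 1")
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  bad <- exons$end > chrom_len[exons$chrom] | exons$start < 0
  if (any(bad | is.na(bad)))
    abort("exon interval(s) outside genome bounds")
  occ <- kmer_occurrences(genome, k)
  seqs <- as.character(genome)
  per_exon <- vapply(seq_len(nrow(exons)), function(i) {
    e <- exons[i, ]
    len <- e$end - e$start
    if (len < k) return(0L)
    s <- substr(seqs[[e$chrom]], e$start + 1L, e$end)
    kmers <- substring(s, 1:(len - k + 1), k:len)
    sum(occ[kmers] == 1L)
  }, 0L)
  tibble(gene_id = exons$gene_id,
         exon_len = exons$end - exons$start,
         mappable = per_exon) %>%
    group_by(.data$gene_id) %>%
    summarise(length = sum(.data$exon_len),
              mappable_length = sum(.data$mappable), .groups = "drop")
}
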