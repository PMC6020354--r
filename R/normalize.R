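# Filtering and transformation of raw matrices into the log2,
# length-corrected, precision-weighted form consumed by the divergence tests.

#' Detectability filter across species
#'
#' A gene is kept iff, in every species, at least `min_individuals` samples
#' have at least `min_reads` reads. This is the joint-quantifiability filter
#' applied before any cross-species testing.
#'
#' @param counts gene x sample count matrix.
#' @param samples sample metadata tibble (sample_id, species, ...). Must cover
#'   every column of `counts`.
#' @param min_reads minimum read count per sample (default 1).
#' @param min_individuals minimum qualifying samples per species (default 3).
#' @return Named logical vector over genes (TRUE = kept).
#' @export
filter_detectable <- function(counts, samples, min_reads = 1,
                              min_individuals = 3) {
  assert_count_matrix(counts)
  info <- sample_info_for(counts, samples)
  per_sp <- table(info$species)
  bad <- names(per_sp)[per_sp < min_individuals]
  if (length(bad))
    abort(paste0("species with fewer than ", min_individuals, " samples: ",
                 paste(bad, collapse = ", ")))
  keep <- rep(TRUE, nrow(counts))
  for (s in unique(info$species)) {
    cols <- info$sample_id[info$species == s]
    keep <- keep &
      rowSums(counts[, cols, drop = FALSE] >= min_reads) >= min_individuals
  }
  setNames(keep, rownames(counts))
}

#' Classify genes as expressed in / specific to species
#'
#' For genes not quantifiable in all species, decides per species whether the
#' gene is expressed there (mean within-species linear RPKM above
#' `q1_threshold` and >= `min_individuals` samples with >= 1 read) and whether
#' it is specific to a single species (expressed there and quantifiable in at
#' most one individual of each other species).
#'
#' @param counts gene x sample count matrix (same genes/samples as `rpkm`).
#' @param rpkm gene x sample log2-RPKM matrix.
#' @param samples sample metadata.
#' @param q1_threshold expression threshold on the linear RPKM scale
#'   (conventionally the first quartile of mean RPKM among detectable genes;
#'   see [rpkm_q1_threshold()]).
#' @param min_individuals minimum qualifying individuals (default 3).
#' @return Tibble: gene_id, detectable_all_species, expressed_in (list column
#'   of species), specific_to (species or NA).
#' @export
classify_expression_categories <- function(counts, rpkm, samples,
                                           q1_threshold,
                                           min_individuals = 3) {
  assert_count_matrix(counts)
  if (q1_threshold <= 0) abort("`q1_threshold` must be positive")
  stopifnot(identical(dim(counts), dim(rpkm)),
            identical(rownames(counts), rownames(rpkm)))
  info <- sample_info_for(counts, samples)
  sp <- unique(info$species)
  expressed <- quantifiable <- n_quant <-
    matrix(FALSE, nrow(counts), length(sp), dimnames = list(rownames(counts), sp))
  n_quant <- matrix(0L, nrow(counts), length(sp),
                    dimnames = list(rownames(counts), sp))
  for (s in sp) {
    cols <- info$sample_id[info$species == s]
    mean_rpkm <- rowMeans(2^rpkm[, cols, drop = FALSE])
    n_quant[, s] <- rowSums(counts[, cols, drop = FALSE] >= 1)
    expressed[, s] <- mean_rpkm > q1_threshold & n_quant[, s] >= min_individuals
  }
  detectable <- filter_detectable(counts, samples,
                                  min_individuals = min_individuals)
  specific <- rep(NA_character_, nrow(counts))
  for (s in sp) {
    others <- setdiff(sp, s)
    only_here <- expressed[, s] & !apply(expressed[, others, drop = FALSE], 1, any) &
      apply(n_quant[, others, drop = FALSE] <= 1, 1, all)
    specific[only_here] <- s
  }
  tibble(gene_id = rownames(counts),
         detectable_all_species = unname(detectable),
         expressed_in = lapply(seq_len(nrow(expressed)),
                               function(i) sp[expressed[i, ]]),
         specific_to = specific)
}

#' First-quartile expression threshold
#'
#' Computes the first quartile of mean within-species linear RPKM over
#' detectable genes, pooling the per-species means. Used as the default
#' `q1_threshold` of [classify_expression_categories()].
#'
#' @param rpkm gene x sample log2-RPKM matrix of detectable genes.
#' @param samples sample metadata.
#' @return A single positive number (linear RPKM scale).
#' @export
rpkm_q1_threshold <- function(rpkm, samples) {
  info <- sample_info_for(rpkm, samples)
  means <- lapply(unique(info$species), function(s)
    rowMeans(2^rpkm[, info$sample_id[info$species == s], drop = FALSE]))
  unname(quantile(unlist(means), 0.25))
}

#' Trimmed mean of M-values normalization factors
#'
#' Composition-robust between-sample scaling factors for count libraries
#' (weighted trimmed mean of log ratios against a reference column, the
#' standard TMM procedure as implemented in edgeR). Factors are scaled so
#' their geometric mean is 1.
#'
#' @param counts gene x sample count matrix (>= 2 samples, no all-zero
#'   column).
#' @param logratio_trim two-sided trim fraction on M-values (default 0.30).
#' @param abs_trim two-sided trim fraction on A-values (default 0.05).
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05) {
  assert_count_matrix(counts)
  if (ncol(counts) < 2) abort("TMM needs at least 2 samples")
  zero <- colSums(counts) == 0
  if (any(zero))
    abort(paste0("all-zero column(s): ",
                 paste(colnames(counts)[zero], collapse = ", ")))
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = logratio_trim,
                              sumTrim = abs_trim)
  setNames(as.numeric(f), colnames(counts))
}

#' Counts to log2 counts-per-million
#'
#' `log2((count + prior) / (libsize * factor + 2 * prior) * 1e6)`, the
#' offset-stabilised log-CPM used throughout the pipeline (matching the form
#' the precision-weight estimator models).
#'
#' @param counts gene x sample count matrix.
#' @param factors per-sample normalization factors from [tmm_factors()]
#'   (default all 1).
#' @param prior_count positive offset (default 0.5).
#' @return gene x sample matrix of log2 CPM values.
#' @export
counts_to_log2cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  assert_count_matrix(counts)
  if (prior_count <= 0) abort("`prior_count` must be positive")
  if (is.null(factors)) factors <- setNames(rep(1, ncol(counts)),
                                            colnames(counts))
  lib <- colSums(counts) * factors[colnames(counts)]
  t(log2(t(counts + prior_count) / (lib + 2 * prior_count) * 1e6))
}

#' log2 CPM to log2 RPKM with species-specific gene lengths
#'
#' Subtracts `log2(length / 1000)` from each value, choosing each gene's
#' length according to the species of the sample (so orthologous genes whose
#' exonic length differs between species are put on a comparable scale).
#'
#' @param expr gene x sample log2-CPM matrix.
#' @param lengths tibble with columns gene_id, species, length and optionally
#'   mappable_length.
#' @param samples sample metadata (provides each sample's species).
#' @param use_mappable use the `mappable_length` column instead of `length`.
#' @return gene x sample matrix of log2 RPKM values.
#' @export
log2cpm_to_log2rpkm <- function(expr, lengths, samples, use_mappable = FALSE) {
  info <- sample_info_for(expr, samples)
  len_col <- if (use_mappable) "mappable_length" else "length"
  if (use_mappable && !"mappable_length" %in% names(lengths))
    abort("`lengths` has no mappable_length column")
  out <- expr
  for (s in unique(info$species)) {
    ls <- lengths[lengths$species == s, ]
    len <- ls[[len_col]][match(rownames(expr), ls$gene_id)]
    missing <- rownames(expr)[is.na(len) | len <= 0]
    if (length(missing))
      abort(paste0("missing/invalid ", len_col, " for species ", s, ": ",
                   paste(head(missing, 5), collapse = ", "),
                   if (length(missing) > 5) " ..."))
    cols <- info$sample_id[info$species == s]
    out[, cols] <- expr[, cols, drop = FALSE] - log2(len / 1000)
  }
  out
}

#' Observation-level precision weights for count data
#'
#' Models the mean-variance trend of log-CPM values (gene-wise least-squares
#' fit, locally weighted regression of sqrt residual SD on average log count)
#' and returns per-observation inverse-variance weights, via the voom
#' procedure. The trend is floored so weights stay finite on degenerate
#' (zero-residual) inputs.
#'
#' @param counts gene x sample count matrix.
#' @param design sample-level design matrix (full rank).
#' @param factors normalization factors from [tmm_factors()] (default 1).
#' @param span lowess span (default 0.5).
#' @param trend_floor lower bound on the fitted sqrt-SD trend (default 1e-4).
#' @return List of class `expr_weights` with `values` (log2 CPM matrix) and
#'   `weights` (strictly positive matrix, same shape).
#' @export
estimate_precision_weights <- function(counts, design, factors = NULL,
                                       span = 0.5, trend_floor = 1e-4) {
  assert_count_matrix(counts)
  design <- as.matrix(design)
  if (nrow(design) != ncol(counts))
    abort("`design` must have one row per sample")
  if (ncol(design) >= ncol(counts))
    abort("fewer samples than design columns")
  if (qr(design)$rank < ncol(design)) abort("`design` is not full rank")
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  lib <- colSums(counts) * factors
  v <- tryCatch(
    suppressWarnings(limma::voom(counts, design = design, lib.size = lib,
                                 span = span)),
    error = function(e) NULL)
  if (is.null(v)) {
    # degenerate input (e.g. zero residual SD everywhere): no usable
    # mean-variance trend; fall back to the floored-trend constant weight
    vals <- t(log2(t(counts + 0.5) / (lib + 1) * 1e6))
    w <- matrix(trend_floor^-4, nrow(counts), ncol(counts),
                dimnames = dimnames(vals))
    return(structure(list(values = vals, weights = w),
                     class = "expr_weights"))
  }
  w <- pmin(v$weights, trend_floor^-4)
  dimnames(w) <- dimnames(v$E)
  structure(list(values = v$E, weights = w), class = "expr_weights")
}

#' Center SILAC log-ratio columns at their trimmed means
#'
#' Shifts each sample (column) so that its trimmed mean over non-missing
#' values is zero; the top and bottom `trim` fractions of genes are excluded
#' from the mean. Missing values are preserved.
#'
#' @param ratios gene x sample matrix of protein log ratios (may contain NA).
#' @param trim two-sided trim fraction (< 0.5; default 0.30).
#' @return Centered matrix of the same shape.
#' @export
center_silac <- function(ratios, trim = 0.30) {
  if (!is.matrix(ratios)) abort("`ratios` must be a matrix")
  if (trim >= 0.5) abort("`trim` must be < 0.5")
  n_ok <- colSums(!is.na(ratios))
  if (any(n_ok == 0))
    abort(paste0("column(s) with all-missing values: ",
                 paste(colnames(ratios)[n_ok == 0], collapse = ", ")))
  if (any(n_ok < 3))
    abort("each column needs >= 3 non-missing values")
  shifts <- apply(ratios, 2, function(x) mean(x, trim = trim, na.rm = TRUE))
  sweep(ratios, 2, shifts)
}

#' Filter protein matrix to genes quantified in enough individuals per species
#'
#' @param ratios gene x sample protein log-ratio matrix (NA = missing).
#' @param samples sample metadata.
#' @param min_individuals minimum non-missing individuals per species
#'   (default 3).
#' @return Named logical vector over genes.
#' @export
filter_protein_quantified <- function(ratios, samples, min_individuals = 3) {
  info <- sample_info_for(ratios, samples)
  keep <- rep(TRUE, nrow(ratios))
  for (s in unique(info$species)) {
    cols <- info$sample_id[info$species == s]
    keep <- keep &
      rowSums(!is.na(ratios[, cols, drop = FALSE])) >= min_individuals
  }
  setNames(keep, rownames(ratios))
}
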