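# End-to-end orchestration: detectability filter -> normalisation ->
# precision weights -> batch adjustment -> subset to matched individuals ->
# divergence / TE / buffering tests -> propagation, with a manifest that
# records the gene count surviving every filter.

subset_layer <- function(x, genes = NULL, cols = NULL) {
  pick <- function(m) {
    if (!is.null(genes)) m <- m[genes, , drop = FALSE]
    if (!is.null(cols)) m <- m[, intersect(colnames(m), cols), drop = FALSE]
    m
  }
  if (inherits(x, "expr_weights"))
    structure(list(values = pick(x$values), weights = pick(x$weights)),
              class = "expr_weights")
  else pick(x)
}

#' Run the full cross-species divergence/buffering pipeline
#'
#' Executes the stages in order on a multi-omic dataset (typically a
#' [simulate_multiomic()] result or [read_multiomic()] output): joint
#' detectability filter on the RNA and ribosome-occupancy counts, TMM
#' normalisation to log2 RPKM with species-specific lengths, precision
#' weights, empirical-Bayes batch adjustment of each count layer (protecting
#' species), SILAC trimmed-mean centering and the >= 3-individuals protein
#' filter, subsetting to the joint three-datatype gene set (and optionally to
#' a matched-individual subset), then the species-divergence, TE-divergence,
#' and two-stage buffering tests per species pair, and the propagation r^2
#' curve. When the dataset carries a truth table a truth-evaluation report
#' (sensitivity / empirical FDR per test) is added.
#'
#' @param dataset list with rna_counts, rpf_counts, protein_ratios, samples,
#'   gene_lengths and optionally truth.
#' @param pairs list of species pairs (default: all pairs).
#' @param alpha FWER cutoff (default 0.05).
#' @param min_individuals detectability / protein completeness requirement.
#' @param use_mappable use mappable gene lengths where available.
#' @param keep_individuals optional individuals to retain for testing after
#'   batch adjustment (samples outside the list still inform batch
#'   estimation).
#' @param outdir optional directory; stage outputs are written as TSV.
#' @param qvalues compute Storey q-values on each test (default TRUE).
#' @return List of class `pipeline_run`: `expr` (normalised layers),
#'   `divergence` (ribosome occupancy), `rna_divergence`,
#'   `protein_divergence`, `te`, `buffering_translational`,
#'   `buffering_posttranslational`, `propagation`, `truth_eval` (or NULL),
#'   and `manifest`.
#' @export
run_pipeline <- function(dataset, pairs = NULL, alpha = 0.05,
                         min_individuals = 3, use_mappable = FALSE,
                         keep_individuals = NULL, outdir = NULL,
                         qvalues = TRUE) {
  samples <- dataset$samples
  sp <- unique(samples$species)
  if (is.null(pairs)) pairs <- utils::combn(sp, 2, simplify = FALSE)
  for (p in pairs)
    if (length(p) != 2 || !all(p %in% sp))
      abort(paste0("invalid species pair: ", paste(p, collapse = ", ")))
  manifest <- list()
  note <- function(stage, n_genes, detail = "") {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, n_genes = as.integer(n_genes), detail = detail)
  }
  note("input", nrow(dataset$rna_counts),
       sprintf("%d samples/layer", ncol(dataset$rna_counts)))

  # detectability filter, jointly on both count layers
  keep <- filter_detectable(dataset$rna_counts, samples,
                            min_individuals = min_individuals) &
          filter_detectable(dataset$rpf_counts, samples,
                            min_individuals = min_individuals)
  detectable <- names(keep)[keep]
  note("detectable", length(detectable),
       sprintf(">=1 read in >=%d individuals/species, both count layers",
               min_individuals))

  normalise <- function(counts) {
    counts <- counts[detectable, , drop = FALSE]
    f <- tmm_factors(counts)
    design <- model.matrix(~ 0 + species,
                           data = sample_info_for(counts, samples))
    ew <- estimate_precision_weights(counts, design, f)
    ew$values <- log2cpm_to_log2rpkm(ew$values, dataset$gene_lengths,
                                     samples, use_mappable = use_mappable)
    ew
  }
  rna <- normalise(dataset$rna_counts)
  rpf <- normalise(dataset$rpf_counts)

  adjust <- function(ew) {
    info <- sample_info_for(ew$values, samples)
    if (length(unique(info$batch)) > 1) {
      ew$values <- adjust_batch_eb(ew$values, samples,
                                   protect = "species")$adjusted
    }
    ew
  }
  rna <- adjust(rna)
  rpf <- adjust(rpf)
  note("normalised", length(detectable), "TMM log2RPKM + weights, batch-adjusted")

  prot <- center_silac(dataset$protein_ratios)
  prot_keep <- filter_protein_quantified(prot, samples,
                                         min_individuals = min_individuals)
  joint <- intersect(detectable, names(prot_keep)[prot_keep])
  note("joint_three_datatypes", length(joint),
       sprintf("protein in >=%d individuals/species", min_individuals))

  if (!is.null(keep_individuals)) {
    cols <- samples$sample_id[samples$individual %in% keep_individuals]
    rna <- subset_layer(rna, cols = cols)
    rpf <- subset_layer(rpf, cols = cols)
    prot <- prot[, intersect(colnames(prot), cols), drop = FALSE]
    note("subset_individuals", length(joint),
         sprintf("%d individuals retained", length(keep_individuals)))
  }

  divergence <- species_divergence(rpf, samples, pairs, alpha, qvalues)
  rna_div <- species_divergence(rna, samples, pairs, alpha, qvalues)

  rna_j <- subset_layer(rna, joint)
  rpf_j <- subset_layer(rpf, joint)
  prot_j <- prot[joint, , drop = FALSE]
  prot_div <- species_divergence(prot_j, samples, pairs, alpha, qvalues)

  per_pair <- function(f) {
    res <- lapply(pairs, f)
    dplyr::bind_rows(res)
  }
  te <- per_pair(function(p)
    te_divergence(rna_j, rpf_j, samples, p, alpha, qvalues))
  buf_tl <- per_pair(function(p)
    buffering_test(rna_j, rpf_j, samples, p, alpha, min_individuals, qvalues))
  buf_pt <- per_pair(function(p)
    buffering_test(rpf_j, prot_j, samples, p, alpha, min_individuals, qvalues))
  note("tested", length(joint),
       sprintf("%d pair(s): divergence, TE, buffering", length(pairs)))

  propagation <- lapply(pairs, function(p) {
    cmp <- paste(p, collapse = "_vs_")
    pd <- prot_div[prot_div$comparison == cmp, ]
    rd <- divergence[divergence$comparison == cmp, ]
    nd <- rna_div[rna_div$comparison == cmp, ]
    genes <- Reduce(intersect, list(pd$gene_id, rd$gene_id, nd$gene_id))
    idx <- function(d) match(genes, d$gene_id)
    curve <- propagation_r2(pd$effect[idx(pd)], rd$effect[idx(rd)],
                            nd$effect[idx(nd)], pd$fdr[idx(pd)])
    dplyr::mutate(curve, comparison = cmp, .before = 1)
  })
  propagation <- dplyr::bind_rows(propagation)

  truth_eval <- NULL
  if (!is.null(dataset$truth))
    truth_eval <- evaluate_truth(
      list(divergence = divergence, te = te,
           buffering_translational = buf_tl,
           buffering_posttranslational = buf_pt),
      dataset$truth, pairs)

  manifest <- dplyr::bind_rows(manifest)
  out <- structure(
    list(expr = list(rna = rna, rpf = rpf, protein = prot),
         divergence = divergence, rna_divergence = rna_div,
         protein_divergence = prot_div, te = te,
         buffering_translational = buf_tl,
         buffering_posttranslational = buf_pt,
         propagation = propagation, truth_eval = truth_eval,
         manifest = manifest),
    class = "pipeline_run")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_results(divergence_wide(divergence),
                  file.path(outdir, "divergence_rpf.tsv"))
    write_results(divergence_wide(te), file.path(outdir, "te_divergence.tsv"))
    write_results(divergence_wide(buf_tl),
                  file.path(outdir, "buffering_translational.tsv"))
    write_results(divergence_wide(buf_pt),
                  file.path(outdir, "buffering_posttranslational.tsv"))
    write_results(propagation, file.path(outdir, "propagation.tsv"))
    write_results(manifest, file.path(outdir, "manifest.tsv"))
    if (!is.null(truth_eval))
      write_results(truth_eval, file.path(outdir, "truth_eval.tsv"))
  }
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run\n")
  print(x$manifest)
  invisible(x)
}

#' Evaluate test calls against simulator truth
#'
#' For each test and species pair, computes the number of true positives in
#' the tested set, calls at the FWER cutoff, sensitivity, and empirical FDR
#' among calls. Truth per pair comes from [truth_effect()]: a gene counts as
#' a true positive for the divergence test if its occupancy effect differs
#' between the pair, for the TE test if occupancy and transcript effects
#' differ, and for a buffering test if it carries that buffering class with
#' an upstream effect inside the pair.
#'
#' @param results named list of `divergence_result` tibbles (names among
#'   divergence, te, buffering_translational, buffering_posttranslational).
#' @param truth simulator truth tibble.
#' @param pairs list of species pairs.
#' @return Tibble: test, comparison, n_true, n_called, true_positive_calls,
#'   sensitivity, empirical_fdr.
#' @export
evaluate_truth <- function(results, truth, pairs) {
  rows <- list()
  for (test in names(results)) {
    res <- results[[test]]
    for (p in pairs) {
      cmp_match <- grepl(paste(p, collapse = "_vs_"), res$comparison,
                         fixed = TRUE)
      sub <- res[cmp_match, ]
      if (nrow(sub) == 0) next
      rna_e <- truth_effect(truth, p, "rna")
      rpf_e <- truth_effect(truth, p, "rpf")
      true_pos <- switch(
        test,
        divergence = names(rpf_e)[rpf_e != 0],
        te = names(rpf_e)[(rpf_e - rna_e) != 0],
        buffering_translational = truth$gene_id[
          truth$buffering_class == "translational" & rna_e != 0],
        buffering_posttranslational = truth$gene_id[
          truth$buffering_class == "post_translational" & rpf_e != 0],
        character(0))
      tested <- sub$gene_id[!is.na(sub$p_nominal)]
      tp_set <- intersect(true_pos, tested)
      called <- sub$gene_id[!is.na(sub$significant) & sub$significant]
      rows[[length(rows) + 1]] <- tibble(
        test = test, comparison = paste(p, collapse = "_vs_"),
        n_true = length(tp_set), n_called = length(called),
        true_positive_calls = length(intersect(called, tp_set)),
        sensitivity = if (length(tp_set))
          length(intersect(called, tp_set)) / length(tp_set) else NA_real_,
        empirical_fdr = if (length(called))
          1 - length(intersect(called, tp_set)) / length(called) else 0)
    }
  }
  dplyr::bind_rows(rows)
}
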