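# Post-test analyses: effect-size comparison between regulatory layers,
# divergence-propagation r^2 curves, feature enrichment against buffering
# significance, and the population-variance relaxation test with an
# expression-matched resampled background.

#' Collapse per-isoform feature rows to one row per gene
#'
#' Numeric features are collapsed to the median across isoforms (midpoint
#' convention for even counts); logical features to any-isoform OR.
#'
#' @param features tibble with a gene_id column and feature columns; multiple
#'   rows per gene_id are treated as isoforms.
#' @return One row per gene.
#' @export
collapse_isoform_features <- function(features) {
  features %>%
    group_by(.data$gene_id) %>%
    summarise(across(dplyr::where(is.numeric), ~ median(.x, na.rm = TRUE)),
              across(dplyr::where(is.logical), ~ any(.x, na.rm = TRUE)),
              .groups = "drop")
}

#' Compare effect-size distributions between two layers
#'
#' Wilcoxon rank-sum test on two vectors of absolute log2 effects, e.g.
#' transcript-level vs translation-efficiency divergence among genes diverged
#' at the protein level. Small tie-free inputs use the exact null
#' distribution; otherwise the normal approximation with tie correction is
#' used. Degenerate all-tied input yields p = 1 with a warning.
#'
#' @param effects_a,effects_b numeric vectors of |log2 ratio| effects.
#' @return One-row tibble: statistic (W), p_value, n_a, n_b.
#' @export
compare_effect_sizes <- function(effects_a, effects_b) {
  effects_a <- effects_a[!is.na(effects_a)]
  effects_b <- effects_b[!is.na(effects_b)]
  if (!length(effects_a) || !length(effects_b))
    abort("both effect vectors must be non-empty")
  if (length(unique(c(effects_a, effects_b))) == 1) {
    warn("all effects tied; p set to 1")
    return(tibble(statistic = length(effects_a) * length(effects_b) / 2,
                  p_value = 1, n_a = length(effects_a),
                  n_b = length(effects_b)))
  }
  wt <- suppressWarnings(wilcox.test(effects_a, effects_b, correct = TRUE))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_a = length(effects_a), n_b = length(effects_b))
}

#' Divergence propagation curve (r^2 by protein-FDR cutoff)
#'
#' For each FDR cutoff, restricts to genes whose protein-level divergence FDR
#' is at or below the cutoff and computes the squared Pearson correlation
#' between protein-level and ribosome-occupancy divergence effects, both as
#' given (`r2_raw`) and after regressing transcript-level divergence out of
#' each (`r2_rna_adjusted`). Cutoffs retaining fewer than 3 genes are omitted
#' with a warning.
#'
#' @param protein_div,rpf_div,rna_div per-gene signed log2 divergence effects
#'   (equal length, aligned).
#' @param protein_fdr per-gene FDR (or q-value) for protein-level divergence.
#' @param cutoffs FDR grid in (0, 1].
#' @return Tibble of class `propagation_curve`: cutoff, n_genes, r2_raw,
#'   r2_rna_adjusted.
#' @export
propagation_r2 <- function(protein_div, rpf_div, rna_div, protein_fdr,
                           cutoffs = c(0.01, 0.05, 0.1, 0.2, 0.5)) {
  if (any(cutoffs <= 0 | cutoffs > 1)) abort("cutoffs must lie in (0,1]")
  stopifnot(length(protein_div) == length(rpf_div),
            length(rpf_div) == length(rna_div),
            length(rna_div) == length(protein_fdr))
  rows <- lapply(sort(cutoffs), function(cut) {
    sel <- !is.na(protein_fdr) & protein_fdr <= cut &
      complete.cases(protein_div, rpf_div, rna_div)
    if (sum(sel) < 3) {
      warn(sprintf("cutoff %g retains < 3 genes; omitted", cut))
      return(NULL)
    }
    pd <- protein_div[sel]; rd <- rpf_div[sel]; nd <- rna_div[sel]
    pd_res <- stats::resid(lm(pd ~ nd))
    rd_res <- stats::resid(lm(rd ~ nd))
    tibble(cutoff = cut, n_genes = sum(sel),
           r2_raw = cor(pd, rd)^2,
           r2_rna_adjusted = cor(pd_res, rd_res)^2)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("propagation_curve", class(out))
  out
}

#' Feature enrichment against buffering significance
#'
#' Pearson product-moment correlation between a per-gene feature (numeric or
#' binary) and `-log10` of the nominal buffering p-value; the sign of the
#' correlation gives the direction of enrichment.
#'
#' @param feature per-gene numeric (or logical) vector.
#' @param buffering_p per-gene nominal p-values, aligned with `feature`.
#' @return One-row tibble: r, p_value, n (NA r with a message for
#'   zero-variance features).
#' @export
feature_enrichment <- function(feature, buffering_p) {
  feature <- as.numeric(feature)
  score <- -log10(buffering_p)
  ok <- complete.cases(feature, score) & is.finite(score)
  if (sum(ok) < 3) abort("need >= 3 complete pairs")
  if (sd(feature[ok]) == 0) {
    rlang::inform("zero-variance feature; correlation undefined")
    return(tibble(r = NA_real_, p_value = NA_real_, n = sum(ok)))
  }
  ct <- cor.test(feature[ok], score[ok])
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Enrichment scan over a feature table
#'
#' Applies [feature_enrichment()] to every feature column and adjusts the
#' p-values across features with Benjamini-Hochberg (the convention used for
#' term-membership scans such as GO).
#'
#' @param features tibble with gene_id plus feature columns.
#' @param buffering tibble with gene_id and p_nominal (e.g. a
#'   `divergence_result` from [buffering_test()]).
#' @return Tibble: feature, r, p_value, n, p_adjusted.
#' @export
enrich_features <- function(features, buffering) {
  merged <- dplyr::inner_join(features,
                              buffering[, c("gene_id", "p_nominal")],
                              by = "gene_id")
  cols <- setdiff(names(features), "gene_id")
  rows <- lapply(cols, function(cl) {
    res <- feature_enrichment(merged[[cl]], merged$p_nominal)
    dplyr::mutate(res, feature = cl, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}

#' Population-variance relaxation test for buffered genes
#'
#' Asks whether buffered genes show elevated expression variability across a
#' within-species population panel. Per-gene variability is the SD across
#' individuals. In unmatched mode the statistic is the Pearson enrichment of
#' SD against `-log10(p)` (as in [feature_enrichment()]). In matched mode the
#' buffered set is genes with Bonferroni FWER at or below `alpha`; background
#' sets of the same size are resampled from the remaining genes preserving
#' the buffered set's expression-level bin histogram (`n_bins` quantile bins
#' of `expr_level`), and the empirical p-value is
#' `(1 + #\{null mean SD >= observed\}) / (1 + n_resample)`.
#' Bins with no background genes are merged downward with a warning.
#'
#' @param pop_expr gene x individual expression matrix (one species
#'   population, >= 10 individuals).
#' @param buffering_p per-gene nominal buffering p-values aligned with the
#'   rows of `pop_expr`.
#' @param expr_level per-gene mean expression used for matching (default:
#'   row means of `pop_expr`).
#' @param matched use the expression-matched resampling test (default TRUE).
#' @param alpha FWER cutoff defining the buffered set (default 0.05).
#' @param n_bins number of expression bins (default 10).
#' @param n_resample background resamples (default 1000).
#' @param seed integer seed for the resampling.
#' @return One-row tibble: mode, statistic (observed mean SD or enrichment
#'   r), null_mean (matched mode), p_value, n_buffered.
#' @export
variance_relaxation <- function(pop_expr, buffering_p,
                                expr_level = rowMeans(pop_expr, na.rm = TRUE),
                                matched = TRUE, alpha = 0.05, n_bins = 10,
                                n_resample = 1000, seed = 1L) {
  if (ncol(pop_expr) < 10) abort("population panel needs >= 10 individuals")
  if (nrow(pop_expr) != length(buffering_p))
    abort("`buffering_p` must align with the rows of `pop_expr`")
  gene_sd <- apply(pop_expr, 1, sd, na.rm = TRUE)
  if (!matched) {
    res <- feature_enrichment(gene_sd, buffering_p)
    return(tibble(mode = "unmatched", statistic = res$r,
                  null_mean = NA_real_, p_value = res$p_value,
                  n_buffered = NA_integer_))
  }
  fwer <- p.adjust(buffering_p, method = "bonferroni")
  buffered <- which(!is.na(fwer) & fwer <= alpha)
  if (length(buffered) < 2) abort("fewer than 2 buffered genes at the cutoff")
  background <- setdiff(seq_along(buffering_p), buffered)
  bin <- cut(rank(expr_level, ties.method = "first"),
             breaks = n_bins, labels = FALSE)
  obs <- mean(gene_sd[buffered])
  with_sim_seed(seed, {
    draws <- matrix(0, n_resample, length(buffered))
    col_at <- 1L
    for (b in sort(unique(bin[buffered]))) {
      k <- sum(bin[buffered] == b)
      pool <- background[bin[background] == b]
      while (length(pool) == 0) {
        warn(sprintf("no background genes in expression bin %d; merged down", b))
        b <- b - 1L
        if (b < 1) abort("no background genes in any lower bin")
        pool <- background[bin[background] == b]
      }
      idx <- matrix(sample(pool, k * n_resample, replace = TRUE),
                    n_resample, k)
      draws[, col_at:(col_at + k - 1L)] <- matrix(gene_sd[idx], n_resample, k)
      col_at <- col_at + k
    }
    null_dist <- rowMeans(draws)
    p <- (1 + sum(null_dist >= obs)) / (1 + n_resample)
    tibble(mode = "matched", statistic = obs, null_mean = mean(null_dist),
           p_value = p, n_buffered = length(buffered))
  })
}
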