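# Species-divergence tests on the three layers of the expression cascade:
# the fixed-effects species test, the datatype x species interaction test for
# translation-efficiency divergence, and the two-stage regression test for
# buffering, all using gene-wise weighted LS with empirical-Bayes moderated
# t-statistics and Bonferroni/BH/q-value multiple-testing adjustment.

values_of <- function(x) if (inherits(x, "expr_weights")) x$values else x
weights_of <- function(x) if (inherits(x, "expr_weights")) x$weights else NULL

# attach fwer/fdr/qvalue columns, stable gene order
finalize_divergence <- function(tt, comparison, alpha = 0.05,
                                qvalues = TRUE) {
  tt <- tt[order(tt$gene_id), , drop = FALSE]
  out <- tibble(gene_id = tt$gene_id,
                comparison = comparison,
                effect = tt$effect,
                t_mod = tt$t_mod,
                p_nominal = tt$p_nominal,
                fwer = p.adjust(tt$p_nominal, method = "bonferroni"),
                fdr = p.adjust(tt$p_nominal, method = "BH"))
  out$qvalue <- if (qvalues) storey_qvalue(tt$p_nominal) else NA_real_
  out$significant <- !is.na(out$fwer) & out$fwer <= alpha
  class(out) <- c("divergence_result", class(out))
  out
}

check_pair <- function(info, pair, min_individuals = 3) {
  if (length(pair) != 2 || anyDuplicated(pair))
    abort("`pair` must be two distinct species labels")
  n_ind <- vapply(pair, function(s)
    length(unique(info$individual[info$species == s])), 0L)
  if (any(n_ind < min_individuals))
    abort(paste0("species with fewer than ", min_individuals,
                 " individuals: ",
                 paste(pair[n_ind < min_individuals], collapse = ", ")))
}

#' Species divergence test (one layer)
#'
#' Fits, per gene, a fixed-effects species model (cell-means design across
#' all species present) by weighted least squares, moderates the residual
#' variances across genes, and tests each requested pairwise species contrast
#' with moderated t-statistics. The contrast effect is the log2 ratio
#' `pair[1] / pair[2]`.
#'
#' @param expr gene x sample log2 expression matrix, or the
#'   `expr_weights` list from [estimate_precision_weights()] (values +
#'   precision weights).
#' @param samples sample metadata.
#' @param pairs list of length-2 species vectors; default all pairs in order
#'   of appearance.
#' @param alpha FWER significance cutoff for the `significant` flag.
#' @param qvalues compute Storey q-values (default TRUE).
#' @return A `divergence_result` tibble: gene_id, comparison, effect, t_mod,
#'   p_nominal, fwer (Bonferroni), fdr (BH), qvalue, significant; one row per
#'   gene and pair.
#' @export
species_divergence <- function(expr, samples, pairs = NULL, alpha = 0.05,
                               qvalues = TRUE) {
  vals <- values_of(expr)
  w <- weights_of(expr)
  info <- sample_info_for(vals, samples)
  sp <- unique(info$species)
  if (is.null(pairs))
    pairs <- utils::combn(sp, 2, simplify = FALSE)
  for (p in pairs) {
    if (!all(p %in% sp)) abort(paste0("unknown species in pair: ",
                                      paste(p, collapse = ", ")))
    check_pair(info, p)
  }
  species <- factor(info$species, levels = sp)
  design <- model.matrix(~ 0 + species)
  colnames(design) <- sp
  fit <- genewise_fit(vals, design, w)
  mod <- moderate_variances(fit$sigma, fit$df_residual)
  res <- lapply(pairs, function(p) {
    cvec <- as.numeric(sp == p[1]) - as.numeric(sp == p[2])
    tt <- test_coefficient(fit, mod, cvec)
    finalize_divergence(tt, paste(p, collapse = "_vs_"), alpha, qvalues)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("divergence_result", class(out))
  out
}

# match two layers by individual within a species pair; returns aligned
# column indices and the per-individual species/datatype design info
match_individuals <- function(info_a, info_b, pair) {
  a <- info_a[info_a$species %in% pair, ]
  b <- info_b[info_b$species %in% pair, ]
  ind <- intersect(a$individual, b$individual)
  list(ind = ind,
       a = a[match(ind, a$individual), ],
       b = b[match(ind, b$individual), ])
}

#' Translation-efficiency divergence test (interaction model)
#'
#' Jointly models, per gene, the RNA-seq and ribosome-profiling observations
#' of a species pair as `E = mu + b1*S + b2*T + b3*S*T + e`, where `S`
#' indicates the first species of the pair and `T` indicates the
#' ribosome-profiling datatype. The interaction coefficient `b3` is the
#' datatype-dependent species difference, i.e. the log2 ratio of translation
#' efficiency between the species; it is tested with moderated t-statistics.
#' Both layers' precision weights are used when supplied.
#'
#' @param rna,rpf log2 expression for the two layers (matrix or
#'   `expr_weights`). Genes present in only one layer are excluded and
#'   recorded in the `excluded` attribute of the result.
#' @param samples sample metadata (matching is by `individual`).
#' @param pair length-2 species vector; effect sign is pair1 minus pair2.
#' @inheritParams species_divergence
#' @return A `divergence_result` tibble (one row per gene).
#' @export
te_divergence <- function(rna, rpf, samples, pair, alpha = 0.05,
                          qvalues = TRUE) {
  rna_v <- values_of(rna); rpf_v <- values_of(rpf)
  rna_w <- weights_of(rna); rpf_w <- weights_of(rpf)
  info_rna <- sample_info_for(rna_v, samples)
  info_rpf <- sample_info_for(rpf_v, samples)
  m <- match_individuals(info_rna, info_rpf, pair)
  check_pair(dplyr::bind_rows(m$a, m$b), pair)
  genes <- intersect(rownames(rna_v), rownames(rpf_v))
  excluded <- setdiff(union(rownames(rna_v), rownames(rpf_v)), genes)

  acol <- m$a$sample_id; bcol <- m$b$sample_id
  Y <- cbind(rna_v[genes, acol, drop = FALSE],
             rpf_v[genes, bcol, drop = FALSE])
  W <- NULL
  if (!is.null(rna_w) || !is.null(rpf_w)) {
    ones <- function(w, mat, cols) if (is.null(w))
      matrix(1, length(genes), length(cols)) else w[genes, cols, drop = FALSE]
    W <- cbind(ones(rna_w, rna_v, acol), ones(rpf_w, rpf_v, bcol))
  }
  s_ind <- c(as.numeric(m$a$species == pair[1]),
             as.numeric(m$b$species == pair[1]))
  t_ind <- c(rep(0, length(acol)), rep(1, length(bcol)))
  design <- cbind(intercept = 1, species = s_ind, datatype = t_ind,
                  interaction = s_ind * t_ind)
  fit <- genewise_fit(Y, design, W)
  mod <- moderate_variances(fit$sigma, fit$df_residual)
  tt <- test_coefficient(fit, mod, "interaction")
  out <- finalize_divergence(tt, paste0("TE_", paste(pair, collapse = "_vs_")),
                             alpha, qvalues)
  attr(out, "excluded") <- excluded
  out
}

#' Two-stage buffering test
#'
#' Tests, per gene, whether species divergence present in an upstream layer
#' is absent from the next layer down. Stage 1 regresses the upstream trait
#' on the downstream trait (per gene, ordinary LS with intercept); stage 2
#' models the stage-1 residuals with a species indicator, whose coefficient
#' (the residual species divergence of the upstream trait, i.e. the buffering
#' effect size) is tested with moderated t-statistics across genes.
#'
#' Translational buffering: upstream = RNA, downstream = ribosome occupancy.
#' Post-translational buffering: upstream = ribosome occupancy, downstream =
#' protein.
#'
#' Only the two species of `pair` are used. A gene needs at least
#' `min_individuals` individuals per species with both traits non-missing;
#' genes failing this are excluded (NA rows). Genes whose downstream trait
#' has zero variance get a stage-1 slope of 0 (residual = centred upstream)
#' and are flagged.
#'
#' @param upstream,downstream gene x sample log2 matrices (or `expr_weights`;
#'   stage-2 fits are unweighted). Matching is by individual.
#' @param samples sample metadata.
#' @param pair length-2 species vector; effect sign is pair1 minus pair2.
#' @param min_individuals per-species completeness requirement (default 3).
#' @inheritParams species_divergence
#' @return A `divergence_result` tibble with extra columns
#'   `zero_downstream_var` and `n_used`.
#' @export
buffering_test <- function(upstream, downstream, samples, pair,
                           alpha = 0.05, min_individuals = 3,
                           qvalues = TRUE) {
  up_v <- values_of(upstream); dn_v <- values_of(downstream)
  info_up <- sample_info_for(up_v, samples)
  info_dn <- sample_info_for(dn_v, samples)
  m <- match_individuals(info_up, info_dn, pair)
  if (length(m$ind) < 2 * min_individuals)
    abort("too few individuals with both traits measured")
  genes <- intersect(rownames(up_v), rownames(dn_v))
  U <- up_v[genes, m$a$sample_id, drop = FALSE]
  D <- dn_v[genes, m$b$sample_id, drop = FALSE]
  species <- m$a$species
  if (!setequal(unique(species), pair)) check_pair(m$a, pair)

  ok <- !is.na(U) & !is.na(D)
  U[!ok] <- NA; D[!ok] <- NA
  n_sp <- sapply(pair, function(s)
    rowSums(ok[, species == s, drop = FALSE]))
  testable <- n_sp[, 1] >= min_individuals & n_sp[, 2] >= min_individuals
  check_pair(m$a, pair, min_individuals)

  # stage 1: U = mu + b * D, gene-wise OLS (vectorised)
  n_used <- rowSums(ok)
  mu_u <- rowMeans(U, na.rm = TRUE)
  mu_d <- rowMeans(D, na.rm = TRUE)
  Uc <- U - mu_u; Dc <- D - mu_d
  sxx <- rowSums(Dc^2, na.rm = TRUE)
  sxy <- rowSums(Uc * Dc, na.rm = TRUE)
  zero_var <- sxx < 1e-12
  slope <- ifelse(zero_var, 0, sxy / ifelse(zero_var, 1, sxx))
  resid <- Uc - slope * Dc  # NA where incomplete
  resid[!testable, ] <- NA

  # stage 2: residual = mu' + b2 * S
  design <- cbind(intercept = 1,
                  species = as.numeric(species == pair[1]))
  fit <- genewise_fit(resid, design)
  sig_ok <- fit$sigma[is.finite(fit$sigma)]
  if (length(sig_ok) && all(sig_ok < 1e-12)) {
    # perfect propagation for every gene: no residual divergence to test
    tt <- tibble(gene_id = rownames(resid),
                 effect = unname(fit$coefficients[, "species"]),
                 t_mod = 0, p_nominal = 1, df_total = Inf)
  } else {
    mod <- moderate_variances(fit$sigma, fit$df_residual)
    tt <- test_coefficient(fit, mod, "species")
  }
  out <- finalize_divergence(
    tt, paste0("buffering_", paste(pair, collapse = "_vs_")), alpha, qvalues)
  extra <- tibble(gene_id = genes, zero_downstream_var = unname(zero_var),
                  n_used = unname(n_used))
  out <- dplyr::left_join(out, extra, by = "gene_id")
  class(out) <- c("divergence_result", class(out))
  out
}

#' Multiple-testing adjustment
#'
#' @param p vector of p-values in `[0,1]` (NA allowed).
#' @param method "bonferroni" (`min(1, m*p)`), "bh" (step-up FDR), or
#'   "qvalue" (BH-style with the null proportion pi0 estimated by the
#'   smoother method; see [storey_qvalue()]).
#' @return Adjusted vector of the same length.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh", "qvalue")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0,1]")
  switch(method,
         bonferroni = p.adjust(p, method = "bonferroni"),
         bh = p.adjust(p, method = "BH"),
         qvalue = storey_qvalue(p))
}

#' Smoother estimate of the null proportion pi0
#'
#' Evaluates `pi0(lambda) = mean(p > lambda) / (1 - lambda)` on a grid and
#' extrapolates with a df-3 smoothing spline to the largest lambda; the
#' result is clamped to (0, 1].
#'
#' @param p p-values.
#' @param lambda evaluation grid (default 0.05 to 0.95 by 0.05).
#' @return Estimated pi0.
#' @export
storey_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  p <- p[!is.na(p)]
  if (length(p) == 0) return(1)
  pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
  pi0 <- if (length(lambda) >= 4) {
    fit <- smooth.spline(lambda, pi0l, df = 3)
    predict(fit, x = max(lambda))$y
  } else min(pi0l)
  min(max(pi0, 1e-8), 1)
}

#' Storey q-values
#'
#' BH-style step-up quantities scaled by the estimated null proportion:
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`.
#'
#' @param p p-values (NA allowed; returned as NA).
#' @param pi0 null proportion; estimated by [storey_pi0()] if NULL.
#' @return q-values of the same length.
#' @export
storey_qvalue <- function(p, pi0 = NULL) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(out)
  if (is.null(pi0)) pi0 <- storey_pi0(pv)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * pv[o] / (m:1)))[ro]
  out[ok] <- q
  out
}

#' Reshape divergence results to one row per gene
#'
#' Produces the conventional wide layout with per-comparison column blocks
#' `<comparison>.beta`, `<comparison>.p.value`, `<comparison>.FDR`,
#' `<comparison>.FWER`.
#'
#' @param result a `divergence_result` tibble (possibly several comparisons).
#' @return A wide tibble, one row per gene.
#' @export
divergence_wide <- function(result) {
  long <- result %>%
    select("gene_id", "comparison", beta = "effect",
           p.value = "p_nominal", FDR = "fdr", FWER = "fwer")
  tidyr::pivot_wider(long, names_from = "comparison",
                     values_from = c("beta", "p.value", "FDR", "FWER"),
                     names_glue = "{comparison}.{.value}")
}

#' @export
print.divergence_result <- function(x, ...) {
  n_comp <- length(unique(x$comparison))
  cat("Divergence test:", length(unique(x$gene_id)), "genes,",
      n_comp, "comparison(s);",
      sum(x$significant, na.rm = TRUE), "significant at the FWER cutoff\n")
  NextMethod()
}
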