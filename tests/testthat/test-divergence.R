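test_that("species contrasts are antisymmetric under pair reversal", {
  set.seed(6)
  samples <- make_samples(4)
  expr <- gauss_matrix(40, samples)
  ab <- species_divergence(expr, samples, pairs = list(c("human", "chimp")),
                          qvalues = FALSE)
  ba <- species_divergence(expr, samples, pairs = list(c("chimp", "human")),
                          qvalues = FALSE)
  expect_equal(ab$effect, -ba$effect, tolerance = 1e-12)
  expect_equal(ab$p_nominal, ba$p_nominal, tolerance = 1e-12)
})

test_that("species divergence requires three individuals per species", {
  samples <- make_samples(4)
  drop <- samples[!(samples$individual %in% c("chimp_1", "chimp_2")), ]
  expr <- gauss_matrix(30, drop)
  expect_error(species_divergence(expr, drop,
                                  pairs = list(c("human", "chimp"))),
               "fewer than 3")
})

test_that("species divergence matches the reference moderated-t implementation", {
  sim <- simulate_multiomic(sim_config(n_genes = 300, seed = 3))
  keep <- filter_detectable(sim$rpf_counts, sim$samples)
  cnt <- sim$rpf_counts[keep, ]
  f <- tmm_factors(cnt)
  info <- sim$samples[match(colnames(cnt), sim$samples$sample_id), ]
  design <- stats::model.matrix(~ 0 + species, data = info)
  colnames(design) <- sub("species", "", colnames(design))
  ew <- estimate_precision_weights(cnt, design, f)
  res <- species_divergence(ew, sim$samples,
                            pairs = list(c("human", "chimp")), qvalues = FALSE)
  v <- limma::voom(cnt, design, lib.size = colSums(cnt) * f)
  cfit <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(v, design),
    limma::makeContrasts(human - chimp, levels = design)))
  expect_lt(max(abs(res$effect - cfit$coefficients[res$gene_id, 1])), 1e-8)
  expect_lt(max(abs(res$t_mod - cfit$t[res$gene_id, 1])), 1e-8)
  # p-values: with an infinite prior df this package takes the normal limit
  # while the reference caps the t df at a large finite value; agreement is
  # then to ~1e-3 rather than machine precision
  expect_lt(max(abs(res$p_nominal - cfit$p.value[res$gene_id, 1])), 1e-3)
})

test_that("a detectable species effect is found and flagged significant", {
  set.seed(9)
  samples <- make_samples(4, c("human", "chimp"))
  expr <- gauss_matrix(500, samples, sd = 0.3)
  hu <- samples$sample_id[samples$species == "human"]
  expr[1:10, hu] <- expr[1:10, hu] + 2
  res <- species_divergence(expr, samples, pairs = list(c("human", "chimp")),
                            qvalues = FALSE)
  top <- res[match(sprintf("g%03d", 1:10), res$gene_id), ]
  expect_true(all(abs(top$effect - 2) < 0.5))
  expect_true(all(top$significant))
  expect_equal(sum(res$significant), 10)
})

test_that("TE interaction is exactly zero when occupancy tracks transcript", {
  samples_r <- make_samples(4, c("human", "chimp"), datatype = "rna")
  samples_p <- make_samples(4, c("human", "chimp"), datatype = "rpf")
  samples <- dplyr::bind_rows(samples_r, samples_p)
  set.seed(1)
  rna <- gauss_matrix(20, samples_r)
  rpf <- rna + 0.7                      # constant datatype offset, no interaction
  colnames(rpf) <- samples_p$sample_id
  res <- te_divergence(rna, rpf, samples, c("human", "chimp"), qvalues = FALSE)
  expect_lt(max(abs(res$effect)), 1e-10)
})

test_that("TE interaction coefficient matches brute-force OLS", {
  samples_r <- make_samples(3, c("human", "chimp"), datatype = "rna")
  samples_p <- make_samples(3, c("human", "chimp"), datatype = "rpf")
  samples <- dplyr::bind_rows(samples_r, samples_p)
  for (s in 1:4) {
    set.seed(s)
    rna <- gauss_matrix(5, samples_r)
    rpf <- gauss_matrix(5, samples_p)
    w_r <- matrix(runif(30, 0.5, 2), 5, 6)
    w_p <- matrix(runif(30, 0.5, 2), 5, 6)
    dimnames(w_r) <- dimnames(rna); dimnames(w_p) <- dimnames(rpf)
    res <- te_divergence(
      structure(list(values = rna, weights = w_r), class = "expr_weights"),
      structure(list(values = rpf, weights = w_p), class = "expr_weights"),
      samples, c("human", "chimp"), qvalues = FALSE)
    s_ind <- as.numeric(samples_r$species == "human")
    for (g in 1:5) {
      ora <- bf_interaction_coef(rna[g, ], rpf[g, ], s_ind, s_ind,
                                 w_r[g, ], w_p[g, ])
      expect_lt(abs(res$effect[res$gene_id == rownames(rna)[g]] - ora), 1e-10)
    }
  }
})

test_that("genes missing from one datatype are excluded and reported", {
  samples_r <- make_samples(3, c("human", "chimp"), datatype = "rna")
  samples_p <- make_samples(3, c("human", "chimp"), datatype = "rpf")
  samples <- dplyr::bind_rows(samples_r, samples_p)
  set.seed(2)
  rna <- gauss_matrix(6, samples_r)
  rpf <- gauss_matrix(4, samples_p)
  res <- te_divergence(rna, rpf, samples, c("human", "chimp"), qvalues = FALSE)
  expect_setequal(res$gene_id, rownames(rpf))
  expect_setequal(attr(res, "excluded"), setdiff(rownames(rna), rownames(rpf)))
})

test_that("buffering residuals vanish under perfect propagation", {
  samples_u <- make_samples(4, c("human", "chimp"), datatype = "rna")
  samples_d <- make_samples(4, c("human", "chimp"), datatype = "rpf")
  samples <- dplyr::bind_rows(samples_u, samples_d)
  set.seed(5)
  up <- gauss_matrix(15, samples_u)
  dn <- up
  colnames(dn) <- samples_d$sample_id
  res <- buffering_test(up, dn, samples, c("human", "chimp"), qvalues = FALSE)
  expect_lt(max(abs(res$effect)), 1e-10)
})

test_that("two-stage buffering coefficient matches brute-force regression", {
  samples_u <- make_samples(4, c("human", "chimp"), datatype = "rna")
  samples_d <- make_samples(4, c("human", "chimp"), datatype = "rpf")
  samples <- dplyr::bind_rows(samples_u, samples_d)
  s1 <- as.numeric(samples_u$species == "human")
  for (s in 1:4) {
    set.seed(10 + s)
    up <- gauss_matrix(6, samples_u)
    dn <- gauss_matrix(6, samples_d)
    res <- buffering_test(up, dn, samples, c("human", "chimp"), qvalues = FALSE)
    for (g in 1:6) {
      ora <- bf_two_stage_coef(up[g, ], dn[g, ], s1)
      expect_lt(abs(res$effect[res$gene_id == rownames(up)[g]] - ora), 1e-10)
    }
  }
})

test_that("a buffered species effect is recovered from the residuals", {
  set.seed(21)
  samples_u <- make_samples(4, c("human", "chimp"), datatype = "rpf")
  samples_d <- make_samples(4, c("human", "chimp"), datatype = "protein")
  samples <- dplyr::bind_rows(samples_u, samples_d)
  up <- gauss_matrix(400, samples_u, sd = 0.3)
  hu <- samples_u$sample_id[samples_u$species == "human"]
  up[1:20, hu] <- up[1:20, hu] + 2
  dn <- gauss_matrix(400, samples_d, sd = 0.3)   # downstream pure noise
  res <- buffering_test(up, dn, samples, c("human", "chimp"), qvalues = FALSE)
  top <- res[match(sprintf("g%03d", 1:20), res$gene_id), ]
  expect_lt(abs(median(top$effect) - 2), 0.5)
})

test_that("zero-variance downstream genes fall back to a centred residual", {
  samples_u <- make_samples(3, c("human", "chimp"), datatype = "rna")
  samples_d <- make_samples(3, c("human", "chimp"), datatype = "rpf")
  samples <- dplyr::bind_rows(samples_u, samples_d)
  set.seed(3)
  up <- gauss_matrix(4, samples_u)
  dn <- gauss_matrix(4, samples_d)
  dn[2, ] <- 1.5                       # constant downstream
  res <- buffering_test(up, dn, samples, c("human", "chimp"), qvalues = FALSE)
  expect_true(res$zero_downstream_var[res$gene_id == "g002"])
  s1 <- as.numeric(samples_u$species == "human")
  ora <- unname(coef(lm(I(up[2, ] - mean(up[2, ])) ~ s1))[2])
  expect_lt(abs(res$effect[res$gene_id == "g002"] - ora), 1e-10)
})

test_that("p-value adjustment follows Bonferroni, BH and q-value definitions", {
  expect_equal(adjust_pvalues(rep(0.01, 5), "bonferroni"), rep(0.05, 5))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  set.seed(8)
  p <- runif(10000)
  pi0 <- storey_pi0(p)
  expect_gte(pi0, 0.8); expect_lte(pi0, 1.0)
  q <- adjust_pvalues(p, "qvalue")
  expect_true(all(q >= pi0 * p - 1e-12))
  expect_true(all(q <= 1))
  # fwer and fdr never fall below the nominal p
  fw <- adjust_pvalues(p, "bonferroni"); fd <- adjust_pvalues(p, "bh")
  expect_true(all(fw >= p)); expect_true(all(fd >= p - 1e-12))
  expect_identical(adjust_pvalues(numeric(0), "bh"), numeric(0))
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), "0,1")
})

test_that("divergence tables reshape to per-comparison wide columns", {
  set.seed(12)
  samples <- make_samples(3)
  expr <- gauss_matrix(10, samples)
  res <- species_divergence(expr, samples, qvalues = FALSE)
  wide <- divergence_wide(res)
  expect_identical(nrow(wide), 10L)
  expect_true(all(c("human_vs_chimp.beta", "human_vs_chimp.p.value",
                    "human_vs_chimp.FDR", "human_vs_chimp.FWER",
                    "chimp_vs_rhesus.beta") %in% names(wide)))
})
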