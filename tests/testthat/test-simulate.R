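test_that("null configuration yields a fully null truth table", {
  cfg <- sim_config(n_genes = 200, frac_rna_divergent = 0,
                    frac_te_divergent = 0, frac_buffered_translational = 0,
                    frac_buffered_posttranslational = 0, seed = 11)
  sim <- simulate_multiomic(cfg)
  expect_true(all(sim$truth$delta_rna == 0))
  expect_true(all(sim$truth$tau_te == 0))
  expect_true(all(sim$truth$buffering_class == "none"))
})

test_that("divergence-class counts are exact floors of the fractions", {
  cfg <- sim_config(n_genes = 1000, frac_buffered_posttranslational = 0.05,
                    seed = 2)
  sim <- simulate_multiomic(cfg)
  expect_identical(sum(sim$truth$buffering_class == "post_translational"), 50L)
  expect_identical(sum(sim$truth$divergence_class == "te"), 20L)
})

test_that("simulation is deterministic given the config seed", {
  cfg <- sim_config(n_genes = 50, seed = 9)
  a <- simulate_multiomic(cfg)
  b <- simulate_multiomic(cfg)
  expect_identical(a$rna_counts, b$rna_counts)
  expect_identical(a$protein_ratios, b$protein_ratios)
  expect_identical(a$truth, b$truth)
  d <- simulate_multiomic(sim_config(n_genes = 50, seed = 10))
  expect_false(identical(a$rna_counts, d$rna_counts))
})

test_that("replicate count variance matches the NB m + phi*m^2 law", {
  # 400 replicate draws of a small panel with near-constant dispersion and
  # fixed library size; biological noise off to isolate the NB component
  phi <- 0.2
  cfg_for <- function(s) sim_config(
    n_genes = 5, n_per_species = 3, baseline_log2_expr_mean = 3,
    baseline_log2_expr_sd = 0, bio_sd = 0, nb_dispersion_mean = phi,
    nb_dispersion_shape = 1e6, lib_size_range = c(1e5, 1e5),
    frac_rna_divergent = 0, frac_te_divergent = 0,
    frac_buffered_translational = 0, frac_buffered_posttranslational = 0,
    seed = s)
  draws <- vapply(1:400, function(s)
    simulate_multiomic(cfg_for(s))$rna_counts[, 1], numeric(5))
  m <- rowMeans(draws)
  v <- apply(draws, 1, var)
  expected <- m + phi * m^2
  # SE of the sample variance from NB fourth central moment (numeric)
  for (g in 1:5) {
    size <- 1 / phi
    x <- 0:qnbinom(1 - 1e-12, mu = m[g], size = size)
    pr <- dnbinom(x, mu = m[g], size = size)
    mu4 <- sum(pr * (x - sum(pr * x))^4)
    se <- sqrt((mu4 - expected[g]^2 * (400 - 3) / (400 - 1)) / 400)
    expect_lt(abs(v[g] - expected[g]), 3 * se)
    expect_gt(v[g], m[g])  # overdispersed beyond Poisson
  }
})

test_that("propagated species effects appear in the count layers", {
  cfg <- sim_config(n_genes = 300, n_per_species = 20, seed = 5)
  sim <- simulate_multiomic(cfg)
  cpm_r <- counts_to_log2cpm(sim$rpf_counts)
  info <- sim$samples[match(colnames(cpm_r), sim$samples$sample_id), ]
  obs <- rowMeans(cpm_r[, info$species == "chimp"]) -
    rowMeans(cpm_r[, info$species == "human"])
  expected <- -truth_effect(sim$truth, c("human", "chimp"), "rpf")
  div <- expected != 0
  expect_gt(sum(div), 5)
  expect_lt(median(abs(obs[div] - expected[div])), 0.25)
  # unshifted genes stay near zero
  expect_lt(median(abs(obs[!div])), 0.25)
})

test_that("truth table obeys the buffering-class effect rules", {
  sim <- simulate_multiomic(sim_config(n_genes = 2000, seed = 3))
  tr <- sim$truth
  pair <- c("human", "rhesus")
  rna_e <- truth_effect(tr, pair, "rna")
  rpf_e <- truth_effect(tr, pair, "rpf")
  prot_e <- truth_effect(tr, pair, "protein")
  tl <- tr$buffering_class == "translational"
  pt <- tr$buffering_class == "post_translational"
  expect_true(all(rpf_e[tl] == 0))
  expect_true(all(tr$delta_rna[tl] != 0))
  expect_true(all(prot_e[pt] == 0))
  expect_true(all(rpf_e[pt][tr$shifted_species[pt] %in% pair] != 0))
  none <- tr$buffering_class == "none"
  expect_true(all(prot_e[none] == rpf_e[none]))
})

test_that("footprint simulator respects frame weights and determinism", {
  win <- tibble::tibble(chrom = "chr1", start = c(100L, 400L),
                        end = c(200L, 500L), frame_anchor = c(150L, 450L))
  fp0 <- simulate_footprints(win, 500, c(1, 0, 0), seed = 1)
  expect_true(all((fp0$pos - win$frame_anchor[match(fp0$chrom, win$chrom)]) %% 3 == 0 |
                    (fp0$pos - 150L) %% 3 == 0 | (fp0$pos - 450L) %% 3 == 0))
  # every read sits in frame 0 of its own window
  frame_of <- ifelse(fp0$pos < 300, (fp0$pos - 150L) %% 3L, (fp0$pos - 450L) %% 3L)
  expect_true(all(frame_of == 0))

  fp <- simulate_footprints(win, 30000, rep(1 / 3, 3), seed = 2)
  fr <- ifelse(fp$pos < 300, (fp$pos - 150L) %% 3L, (fp$pos - 450L) %% 3L)
  se <- sqrt(30000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(table(fr) - 10000) < 3 * se))

  expect_identical(simulate_footprints(win, 100, seed = 7),
                   simulate_footprints(win, 100, seed = 7))
  empty <- simulate_footprints(win, 0)
  expect_identical(nrow(empty), 0L)
  expect_error(simulate_footprints(win[0, ], 10), "non-empty")
})

test_that("toy genome duplication structure and determinism hold", {
  toy <- simulate_toy_genome(6, 50, n_duplicated = 0, seed = 4)
  chr <- as.character(toy$genome[[1]])
  for (i in seq_len(nrow(toy$exons))) {
    s <- substr(chr, toy$exons$start[i] + 1, toy$exons$end[i])
    expect_identical(length(gregexpr(s, chr, fixed = TRUE)[[1]]), 1L)
  }
  toy2 <- simulate_toy_genome(4, 40, n_duplicated = 4, seed = 4)
  chr2 <- as.character(toy2$genome[[1]])
  for (i in seq_len(nrow(toy2$exons))) {
    s <- substr(chr2, toy2$exons$start[i] + 1, toy2$exons$end[i])
    expect_gte(length(gregexpr(s, chr2, fixed = TRUE)[[1]]), 2L)
  }
  expect_identical(as.character(simulate_toy_genome(3, 30, 1, seed = 8)$genome),
                   as.character(simulate_toy_genome(3, 30, 1, seed = 8)$genome))
  expect_error(simulate_toy_genome(3, 30, n_duplicated = 4), "<=")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(frac_rna_divergent = 0.9,
                          frac_buffered_posttranslational = 0.2), "sum")
  expect_error(sim_config(n_per_species = 2), ">= 3")
  expect_error(sim_config(lib_size_range = c(10, 1)), "increasing")
  expect_error(sim_config(baseline_log2_expr_mean = 50), "non-integrable")
})
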