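test_that("detectability filter applies the per-species rule", {
  samples <- make_samples(4)
  counts <- matrix(5L, 3, 12, dimnames = list(c("a", "b", "c"),
                                              samples$sample_id))
  # a: 3/4 humans, 4/4 chimps, 3/4 rhesus -> kept
  counts["a", c(1, 8, 12)] <- 0L
  counts["b", ] <- 0L                                   # all zero -> dropped
  counts["c", samples$species == "rhesus"] <- c(1L, 1L, 0L, 0L)  # 2/4 -> dropped
  keep <- filter_detectable(counts, samples)
  expect_identical(keep, c(a = TRUE, b = FALSE, c = FALSE))
  expect_error(filter_detectable(counts, samples, min_individuals = 5),
               "fewer than 5")
})

test_that("lowering min_individuals never drops a kept gene", {
  set.seed(1)
  samples <- make_samples(4)
  counts <- matrix(rpois(50 * 12, 2), 50, 12,
                   dimnames = list(sprintf("g%02d", 1:50), samples$sample_id))
  k3 <- filter_detectable(counts, samples, min_individuals = 3)
  k2 <- filter_detectable(counts, samples, min_individuals = 2)
  expect_true(all(k2[k3]))
})

test_that("expression categories follow the threshold and quantifiability rules", {
  samples <- make_samples(4)
  G <- 3
  counts <- matrix(0L, G, 12, dimnames = list(c("hs", "all", "two"),
                                              samples$sample_id))
  rpkm <- matrix(log2(0.01), G, 12, dimnames = dimnames(counts))
  hu <- samples$species == "human"; ch <- samples$species == "chimp"
  # hs: mean RPKM 10 in human only, 0 reads elsewhere -> specific to human
  counts["hs", hu] <- 50L; rpkm["hs", hu] <- log2(10)
  # all: above threshold everywhere
  counts["all", ] <- 50L; rpkm["all", ] <- log2(20)
  # two: above threshold in human but 2 quantifiable chimp individuals
  counts["two", hu] <- 50L; rpkm["two", hu] <- log2(10)
  counts["two", which(ch)[1:2]] <- 3L
  cats <- classify_expression_categories(counts, rpkm, samples,
                                         q1_threshold = 6.05)
  expect_identical(cats$specific_to, c("human", NA, NA))
  expect_identical(cats$expressed_in[[1]], "human")
  expect_setequal(cats$expressed_in[[2]], c("human", "chimp", "rhesus"))
  expect_identical(cats$expressed_in[[3]], "human")
  expect_error(classify_expression_categories(counts, rpkm, samples, 0),
               "positive")
})

test_that("TMM factors match the brute-force trimmed weighted mean", {
  # identical columns -> all factors 1
  even <- matrix(rep(c(10L, 20L, 30L, 5L, 40L), 3), 5, 3,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  expect_equal(unname(tmm_factors(even)), rep(1, 3), tolerance = 1e-12)
  # pure library-size change: doubling all genes of one column keeps factor 1
  dbl <- even; dbl[, 2] <- dbl[, 2] * 2L
  expect_equal(unname(tmm_factors(dbl)), rep(1, 3), tolerance = 1e-12)
  # random matrices against the independent oracle
  for (s in 1:4) {
    set.seed(s)
    m <- matrix(rnbinom(50 * 4, mu = 200 * runif(50, 0.1, 3), size = 5), 50, 4,
                dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:4)))
    expect_lt(max(abs(tmm_factors(m) - bf_tmm(m))), 1e-10)
    expect_lt(abs(exp(mean(log(tmm_factors(m)))) - 1), 1e-12)
  }
  zero <- even; zero[, 3] <- 0L
  expect_error(tmm_factors(zero), "all-zero")
})

test_that("log2 CPM follows its closed form and is monotone", {
  cnt <- matrix(c(0L, 10L, 100L, 5L), 4, 1,
                dimnames = list(paste0("g", 1:4), "s1"))
  cnt2 <- rbind(cnt, matrix(1e6L - 115L, 1, 1,
                            dimnames = list("filler", "s1")))
  v <- counts_to_log2cpm(cnt2, setNames(1, "s1"))
  expect_equal(v["g1", 1], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  expect_lt(abs(v["g1", 1] + 1), 1e-5)
  expect_true(all(diff(v[c("g1", "g4", "g2", "g3"), 1]) > 0))
})

test_that("RPKM conversion uses species-specific lengths and is invertible", {
  samples <- make_samples(2, c("human", "chimp"))
  expr <- matrix(5, 2, 4, dimnames = list(c("g1", "g2"), samples$sample_id))
  lengths <- tibble::tibble(
    gene_id = rep(c("g1", "g2"), 2),
    species = rep(c("human", "chimp"), each = 2),
    length = c(1000L, 900L, 1000L, 1100L))
  r <- log2cpm_to_log2rpkm(expr, lengths, samples)
  hu <- samples$sample_id[samples$species == "human"]
  ch <- samples$sample_id[samples$species == "chimp"]
  expect_equal(r["g1", hu], expr["g1", hu])         # length 1000 -> unchanged
  # inter-species difference shifts by log2(len_chimp / len_human)
  expect_equal(unname(r["g2", hu[1]] - r["g2", ch[1]]),
               log2(1100 / 900), tolerance = 1e-12)
  # invertible given the lengths
  back <- r
  for (s in c("human", "chimp")) {
    cols <- samples$sample_id[samples$species == s]
    len <- lengths$length[lengths$species == s][match(rownames(r),
      lengths$gene_id[lengths$species == s])]
    back[, cols] <- r[, cols] + log2(len / 1000)
  }
  expect_equal(back, expr, tolerance = 1e-12)
  expect_error(log2cpm_to_log2rpkm(expr, lengths[-1, ], samples), "missing")
})

test_that("precision weights are positive, shaped like the data, and track dispersion", {
  samples <- make_samples(4)
  design <- stats::model.matrix(~species, data = samples)
  set.seed(2)
  draw <- function(phi) matrix(
    rnbinom(300 * 12, mu = rep(exp(runif(300, 3, 7)), 12), size = 1 / phi),
    300, 12, dimnames = list(sprintf("g%03d", 1:300), samples$sample_id))
  lo <- estimate_precision_weights(draw(0.01), design)
  hi <- estimate_precision_weights(draw(0.3), design)
  expect_identical(dim(lo$weights), dim(lo$values))
  expect_true(all(lo$weights > 0))
  expect_gt(mean(lo$weights), mean(hi$weights))
  # degenerate constant counts: trend floored, weights finite
  const <- matrix(50L, 30, 12, dimnames = list(sprintf("g%02d", 1:30),
                                               samples$sample_id))
  w <- estimate_precision_weights(const, design)
  expect_true(all(is.finite(w$weights)))
})

test_that("SILAC centering zeroes the trimmed mean and preserves missingness", {
  sym <- matrix(c(-2, -1, 0, 1, 2), 5, 1, dimnames = list(NULL, "s1"))
  expect_equal(center_silac(sym, 0.30), sym)
  m <- matrix(c(0, 1, 2, 3, 100), 5, 1, dimnames = list(NULL, "s1"))
  expect_equal(center_silac(m, 0.30), m - 2)
  # shift invariance
  expect_equal(center_silac(m + 7, 0.30), center_silac(m, 0.30))
  # trimmed mean of output is 0; NA preserved
  set.seed(3)
  big <- matrix(rnorm(600, 2), 100, 6,
                dimnames = list(NULL, paste0("s", 1:6)))
  big[sample(600, 40)] <- NA
  out <- center_silac(big)
  expect_identical(is.na(out), is.na(big))
  tm <- apply(out, 2, mean, trim = 0.30, na.rm = TRUE)
  expect_lt(max(abs(tm)), 1e-10)
  allna <- big; allna[, 2] <- NA
  expect_error(center_silac(allna), "all-missing")
})

test_that("protein quantification filter needs enough individuals per species", {
  samples <- make_samples(4, datatype = "protein")
  m <- matrix(rnorm(24), 2, 12, dimnames = list(c("g1", "g2"),
                                                samples$sample_id))
  m["g2", which(samples$species == "chimp")[1:2]] <- NA
  keep <- filter_protein_quantified(m, samples)
  expect_identical(keep, c(g1 = TRUE, g2 = FALSE))
})
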