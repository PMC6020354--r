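# Independent brute-force oracles and small fixture builders. These
# deliberately use different code paths (explicit loops, naive algebra) than
# the package implementation.

make_samples <- function(n_per = 4, species = c("human", "chimp", "rhesus"),
                         datatype = "rna") {
  ind <- paste(rep(species, each = n_per), rep(seq_len(n_per), length(species)),
               sep = "_")
  tibble::tibble(sample_id = paste(ind, datatype, sep = "."),
                 individual = ind,
                 species = rep(species, each = n_per),
                 datatype = datatype,
                 batch = "b1",
                 sex = "F")
}

# gene x sample Gaussian fixture with named dims
gauss_matrix <- function(G, samples, sd = 0.3, mean = 0) {
  matrix(rnorm(G * nrow(samples), mean, sd), G, nrow(samples),
         dimnames = list(sprintf("g%03d", seq_len(G)), samples$sample_id))
}

# --- TMM brute force (published definition: weighted doubly trimmed mean of
# --- M-values vs the upper-quartile reference column) -----------------------
bf_tmm <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; rf <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    logR <- log2((obs / nO) / (rf / nR))
    absE <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - rf) / nR / rf
    fin <- is.finite(logR) & is.finite(absE) & absE > -1e10
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * abs_trim) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }, 0)
  f / exp(mean(log(f)))
}

# --- weighted least squares by explicit normal equations --------------------
bf_wls <- function(y, X, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  A <- matrix(0, ncol(X), ncol(X))
  b <- numeric(ncol(X))
  for (i in seq_along(y)) {
    A <- A + w[i] * (X[i, ] %o% X[i, ])
    b <- b + w[i] * y[i] * X[i, ]
  }
  beta <- solve(A, b)
  res <- y - as.vector(X %*% beta)
  rss <- sum(w * res^2)
  df <- length(y) - ncol(X)
  list(coef = beta, sigma = sqrt(rss / df),
       stdev_unscaled = sqrt(diag(solve(A))), df = df)
}

# interaction coefficient of the stacked RNA/RPF model via lm()
bf_interaction_coef <- function(rna_y, rpf_y, s_rna, s_rpf,
                                w_rna = NULL, w_rpf = NULL) {
  y <- c(rna_y, rpf_y)
  S <- c(s_rna, s_rpf)
  Tt <- c(rep(0, length(rna_y)), rep(1, length(rpf_y)))
  w <- if (is.null(w_rna)) NULL else c(w_rna, w_rpf)
  unname(coef(lm(y ~ S * Tt, weights = w))["S:Tt"])
}

# two-stage buffering coefficient via lm()
bf_two_stage_coef <- function(u, d, s1) {
  r <- resid(lm(u ~ d))
  unname(coef(lm(r ~ s1))[2])
}

# mappable length per gene via an explicit k-mer dictionary over both strands
bf_kmer_mappable <- function(genome_chr, exons, k) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  n <- nchar(genome_chr)
  dict <- new.env(hash = TRUE)
  for (i in 1:(n - k + 1)) {
    km <- substr(genome_chr, i, i + k - 1)
    dict[[km]] <- (dict[[km]] %||% 0L) + 1L
  }
  occ <- function(km) {
    (dict[[km]] %||% 0L) + (dict[[rc(km)]] %||% 0L)
  }
  out <- integer(nrow(exons))
  for (e in seq_len(nrow(exons))) {
    len <- exons$end[e] - exons$start[e]
    if (len < k) next
    cnt <- 0L
    for (i in seq_len(len - k + 1)) {
      km <- substr(genome_chr, exons$start[e] + i, exons$start[e] + i + k - 1)
      if (occ(km) == 1L) cnt <- cnt + 1L
    }
    out[e] <- cnt
  }
  tapply(out, exons$gene_id, sum)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exact two-sided rank-sum p-value by full enumeration (no ties assumed)
bf_exact_wilcox_p <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  ws <- apply(combos, 2, function(idx) sum(r[idx])) - n * (n + 1) / 2
  mu <- n * m / 2
  mean(abs(ws - mu) >= abs(w_obs - mu))
}

# quick normalisation of one count layer to weighted log2 RPKM
normalise_layer <- function(counts, sim, keep = NULL) {
  if (!is.null(keep)) counts <- counts[keep, , drop = FALSE]
  f <- tmm_factors(counts)
  info <- sim$samples[match(colnames(counts), sim$samples$sample_id), ]
  design <- stats::model.matrix(~species, data = info)
  ew <- estimate_precision_weights(counts, design, f)
  ew$values <- log2cpm_to_log2rpkm(ew$values, sim$gene_lengths, sim$samples)
  ew
}
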