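# Synthetic multi-omic data with known truth.
#
# The generator emulates the statistical structure the divergence analysis
# assumes: three species, a handful of individuals each, negative-binomial
# sequencing counts whose log-scale species effects either propagate down the
# cascade (RNA -> ribosome occupancy -> protein) or are cut off at a chosen
# layer (translational / post-translational buffering), Gaussian SILAC-style
# protein log ratios, and optional batch location/scale effects on the
# ribosome-profiling layer.

#' Configuration for the multi-omic simulator
#'
#' Builds a validated configuration for [simulate_multiomic()]. Defaults
#' describe the study design the package targets: three primate-like species
#' with four individuals each, ~5000 genes, a log2 species effect of 2 for
#' divergent genes, within-species biological SD of 0.3 log2 units, a small
#' set of translation-efficiency divergent genes (log2 effect 1), and many
#' more post-translationally than translationally buffered genes.
#'
#' Divergence classes are disjoint; each divergent gene carries its offset in
#' exactly one randomly chosen non-reference species (the first species label
#' is the reference, so pairwise effects are differences of per-species
#' offsets).
#'
#' @param n_genes number of genes.
#' @param n_per_species individuals per species (>= 3).
#' @param species ordered species labels; the first is the reference.
#' @param baseline_log2_expr_mean,baseline_log2_expr_sd distribution of
#'   per-gene baseline log2 expression.
#' @param bio_sd within-species biological SD (log2 scale).
#' @param nb_dispersion_mean,nb_dispersion_shape per-gene negative-binomial
#'   dispersions are drawn from a gamma distribution with this mean and shape.
#' @param lib_size_range range (pair) of per-sample library sizes.
#' @param frac_rna_divergent,rna_effect_log2 fraction of genes with a
#'   transcript-level species effect that propagates down the cascade, and its
#'   log2 magnitude.
#' @param frac_te_divergent,te_effect_log2 fraction of genes with a
#'   translation-efficiency offset (ribosome occupancy shifted beyond RNA).
#' @param frac_buffered_translational fraction of genes diverged at the
#'   transcript level but with zero ribosome-occupancy species effect.
#' @param frac_buffered_posttranslational fraction of genes diverged at the
#'   ribosome-occupancy level but with zero protein species effect.
#' @param protein_noise_sd SD of Gaussian noise on protein log ratios.
#' @param protein_missing_rate per-observation missingness rate for protein.
#' @param n_batches number of processing batches for the ribosome-profiling
#'   layer; samples are assigned round-robin within species so batch and
#'   species are never confounded.
#' @param batch_shift_sd,batch_scale_sd SDs of the per-batch per-gene additive
#'   (log2) shift and multiplicative noise-scale effects.
#' @param feature_base_rate,feature_buffering_logfc Poisson rate of simulated
#'   post-translational-modification site counts and the log fold increase for
#'   post-translationally buffered genes (makes enrichment recovery testable).
#' @param seed integer seed; the simulator is deterministic given the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       n_per_species = 4,
                       species = c("human", "chimp", "rhesus"),
                       baseline_log2_expr_mean = 3,
                       baseline_log2_expr_sd = 1.5,
                       bio_sd = 0.28,
                       nb_dispersion_mean = 0.002,
                       nb_dispersion_shape = 10,
                       lib_size_range = c(3e6, 5e6),
                       frac_rna_divergent = 0.10,
                       rna_effect_log2 = 2,
                       frac_te_divergent = 0.02,
                       te_effect_log2 = 1,
                       frac_buffered_translational = 0.004,
                       frac_buffered_posttranslational = 0.04,
                       protein_noise_sd = 0.3,
                       protein_missing_rate = 0.05,
                       n_batches = 1,
                       batch_shift_sd = 0.3,
                       batch_scale_sd = 0.1,
                       feature_base_rate = 3,
                       feature_buffering_logfc = 0.7,
                       seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(frac_rna_divergent, frac_te_divergent,
             frac_buffered_translational, frac_buffered_posttranslational)
  if (any(fracs < 0) || any(fracs > 1) || sum(fracs) > 1)
    abort("divergence-class fractions must lie in [0,1] and sum to at most 1")
  if (n_per_species < 3)
    abort("n_per_species must be >= 3 (joint-analysis filter needs 3 individuals)")
  if (length(species) < 2 || anyDuplicated(species))
    abort("`species` must be >= 2 distinct labels")
  if (length(lib_size_range) != 2 || any(lib_size_range <= 0) ||
      lib_size_range[1] > lib_size_range[2])
    abort("`lib_size_range` must be an increasing positive pair")
  if (nb_dispersion_mean <= 0 || nb_dispersion_shape <= 0 || bio_sd < 0 ||
      protein_noise_sd <= 0)
    abort("dispersion and noise parameters must be positive")
  if (protein_missing_rate < 0 || protein_missing_rate >= 1)
    abort("`protein_missing_rate` must be in [0, 1)")
  if (n_batches < 1) abort("`n_batches` must be >= 1")
  if (abs(baseline_log2_expr_mean) + 6 * baseline_log2_expr_sd +
      abs(rna_effect_log2) + abs(te_effect_log2) > 40)
    abort("expression parameters imply non-integrable (overflowing) count means")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# run code with a local RNG state derived from `seed`
with_sim_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a three-layer multi-omic dataset with known truth
#'
#' Generates RNA-seq and ribosome-profiling count matrices, a protein
#' log-ratio matrix, sample metadata, species-specific gene lengths, and a
#' per-gene truth table. Per gene g and species s, the log2 RNA mean is
#' `mu_g + delta_gs`; the ribosome-occupancy (RPF) mean adds the
#' translation-efficiency offset `tau_gs` (and is reset to `mu_g` for
#' translationally buffered genes); the protein mean equals the RPF species
#' effect unless the gene is post-translationally buffered, in which case it
#' is zero. Counts are negative binomial with per-gene dispersion and
#' per-sample library size; protein values are Gaussian on the log-ratio
#' scale. Batch location/scale effects act on the log-scale RPF means before
#' counts are drawn.
#'
#' @param config a [sim_config()].
#' @return A list of class `multiomic_sim` with elements `rna_counts`,
#'   `rpf_counts` (integer matrices), `protein_ratios` (matrix, may contain
#'   `NA`), `samples` (tibble with sample_id, individual, species, datatype,
#'   batch, sex), `gene_lengths` (tibble gene_id, species, length), `truth`
#'   (tibble gene_id, divergence_class, buffering_class, shifted_species,
#'   delta_rna, tau_te, feature counts), and `config`.
#' @seealso [truth_effect()] to turn the truth table into pairwise effects.
#' @export
simulate_multiomic <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  with_sim_seed(config$seed, {
    G <- config$n_genes
    sp <- config$species
    S <- length(sp)
    n <- config$n_per_species
    gene_id <- sprintf("g%04d", seq_len(G))

    # divergence class assignment (exact floor counts, random genes)
    n_cls <- c(rna = floor(config$frac_rna_divergent * G),
               te = floor(config$frac_te_divergent * G),
               translational = floor(config$frac_buffered_translational * G),
               post_translational = floor(config$frac_buffered_posttranslational * G))
    cls <- rep("none", G)
    picked <- sample.int(G, sum(n_cls))
    cls[picked] <- rep(names(n_cls), n_cls)
    shifted <- ifelse(cls == "none", NA_character_,
                      sample(sp[-1], G, replace = TRUE))
    sign_g <- sample(c(-1, 1), G, replace = TRUE)
    delta_rna <- ifelse(cls %in% c("rna", "translational", "post_translational"),
                        sign_g * config$rna_effect_log2, 0)
    tau_te <- ifelse(cls == "te", sign_g * config$te_effect_log2, 0)

    # per-gene per-species offsets at each layer
    off <- function(effect) {
      m <- matrix(0, G, S, dimnames = list(gene_id, sp))
      has <- !is.na(shifted) & effect != 0
      m[cbind(which(has), match(shifted[has], sp))] <- effect[has]
      m
    }
    off_rna <- off(delta_rna)
    off_rpf <- off_rna + off(tau_te)
    off_rpf[cls == "translational", ] <- 0
    off_prot <- off_rpf
    off_prot[cls == "post_translational", ] <- 0

    mu <- rnorm(G, config$baseline_log2_expr_mean, config$baseline_log2_expr_sd)
    phi <- rgamma(G, shape = config$nb_dispersion_shape,
                  rate = config$nb_dispersion_shape / config$nb_dispersion_mean)
    phi <- pmax(phi, 1e-4)

    individual <- paste(rep(sp, each = n), rep(seq_len(n), S), sep = "_")
    ind_species <- rep(sp, each = n)
    sex <- rep(c("F", "M"), length.out = n)[rep(seq_len(n), S)]
    batch <- paste0("b", ((seq_len(n) - 1L) %% config$n_batches) + 1L)[
      rep(seq_len(n), S)]  # round-robin within species

    lib <- function(k) round(runif(k, config$lib_size_range[1],
                                   config$lib_size_range[2]))
    base_total <- sum(2^mu)

    draw_counts <- function(offsets, batch_eff = NULL) {
      nc <- length(individual)
      m <- matrix(0L, G, nc, dimnames = list(gene_id, individual))
      libs <- lib(nc)
      for (j in seq_len(nc)) {
        s_j <- ind_species[j]
        eps <- rnorm(G, 0, config$bio_sd)
        logmu <- mu + offsets[, s_j]
        if (!is.null(batch_eff)) {
          b <- batch[j]
          logmu <- logmu + batch_eff$shift[, b]
          eps <- eps * batch_eff$scale[, b]
        }
        lam <- 2^(logmu + eps) * libs[j] / base_total
        m[, j] <- rnbinom(G, mu = lam, size = 1 / phi)
      }
      m
    }

    rna_counts <- draw_counts(off_rna)
    batch_eff <- NULL
    if (config$n_batches > 1) {
      bn <- paste0("b", seq_len(config$n_batches))
      batch_eff <- list(
        shift = matrix(rnorm(G * config$n_batches, 0, config$batch_shift_sd),
                       G, config$n_batches, dimnames = list(gene_id, bn)),
        scale = matrix(exp(rnorm(G * config$n_batches, 0, config$batch_scale_sd)),
                       G, config$n_batches, dimnames = list(gene_id, bn)))
    }
    rpf_counts <- draw_counts(off_rpf, batch_eff)

    nu <- rnorm(G, 0, 1)
    prot <- matrix(NA_real_, G, length(individual),
                   dimnames = list(gene_id, individual))
    for (j in seq_along(individual)) {
      prot[, j] <- nu + off_prot[, ind_species[j]] +
        rnorm(G, 0, config$protein_noise_sd)
    }
    if (config$protein_missing_rate > 0) {
      miss <- runif(length(prot)) < config$protein_missing_rate
      prot[miss] <- NA_real_
    }

    # species-specific gene lengths (bp): shared base length, mild jitter
    base_len <- pmax(200L, round(exp(rnorm(G, log(1500), 0.4))))
    gene_lengths <- tibble(
      gene_id = rep(gene_id, S),
      species = rep(sp, each = G),
      length = as.integer(pmax(100L, round(rep(base_len, S) *
                                             runif(G * S, 0.95, 1.05)))))

    is_pt <- cls == "post_translational"
    feat <- function(logfc) rpois(G, config$feature_base_rate *
                                    exp(logfc * is_pt))
    truth <- tibble(
      gene_id = gene_id,
      divergence_class = cls,
      buffering_class = ifelse(cls %in% c("translational", "post_translational"),
                               cls, "none"),
      shifted_species = shifted,
      delta_rna = delta_rna,
      tau_te = tau_te,
      ubiquitination_sites = feat(config$feature_buffering_logfc),
      acetylation_sites = feat(config$feature_buffering_logfc / 2),
      phosphorylation_sites = feat(0))

    samples <- dplyr::bind_rows(lapply(
      c("rna", "rpf", "protein"),
      function(dt) tibble(
        sample_id = paste(individual, dt, sep = "."),
        individual = individual, species = ind_species, datatype = dt,
        batch = if (dt == "rpf") batch else "b1", sex = sex)))

    rename_cols <- function(m, dt) {
      colnames(m) <- paste(colnames(m), dt, sep = ".")
      m
    }
    out <- list(rna_counts = rename_cols(rna_counts, "rna"),
                rpf_counts = rename_cols(rpf_counts, "rpf"),
                protein_ratios = rename_cols(prot, "protein"),
                samples = samples,
                gene_lengths = gene_lengths,
                truth = truth,
                config = config)
    structure(out, class = "multiomic_sim")
  })
}

#' @export
print.multiomic_sim <- function(x, ...) {
  cat("Multi-omic simulation:", nrow(x$rna_counts), "genes,",
      length(unique(x$samples$individual)), "individuals,",
      length(x$config$species), "species\n")
  cat("  divergence classes:",
      paste(names(table(x$truth$divergence_class)),
            table(x$truth$divergence_class), collapse = ", "), "\n")
  invisible(x)
}

#' True pairwise species effect at a given layer
#'
#' Converts the simulator truth table into the signed log2 effect between a
#' pair of species at a chosen layer of the cascade, applying the buffering
#' rules (translational buffering zeroes the ribosome-occupancy effect and
#' everything downstream; post-translational buffering zeroes the protein
#' effect only).
#'
#' @param truth the `truth` tibble from [simulate_multiomic()].
#' @param pair character vector of two species labels; the effect is
#'   `offset(pair[1]) - offset(pair[2])`.
#' @param layer one of "rna", "rpf", "protein".
#' @return Named numeric vector of per-gene effects.
#' @export
truth_effect <- function(truth, pair, layer = c("rna", "rpf", "protein")) {
  layer <- match.arg(layer)
  base <- switch(layer,
    rna = truth$delta_rna,
    rpf = ifelse(truth$buffering_class == "translational", 0,
                 truth$delta_rna + truth$tau_te),
    protein = ifelse(truth$buffering_class %in%
                       c("translational", "post_translational"), 0,
                     truth$delta_rna + truth$tau_te))
  o1 <- ifelse(!is.na(truth$shifted_species) & truth$shifted_species == pair[1],
               base, 0)
  o2 <- ifelse(!is.na(truth$shifted_species) & truth$shifted_species == pair[2],
               base, 0)
  setNames(o1 - o2, truth$gene_id)
}

#' Simulate ribosome-footprint 5' ends within initiation-site windows
#'
#' Draws `n_reads` footprint 5'-end positions uniformly over the supplied
#' windows, with the codon frame of each position (relative to the window's
#' frame anchor) drawn from `frame_weights`. A fixture generator for the
#' codon-periodicity QC.
#'
#' @param tis_windows tibble with columns chrom, start, end (0-based,
#'   half-open) and frame_anchor (genomic position of the first CDS base).
#' @param n_reads number of footprints.
#' @param frame_weights length-3 non-negative vector summing to 1.
#' @param seed integer seed.
#' @param read_length footprint length recorded on each read (default 29).
#' @return Tibble with columns chrom, pos (5'-most base, 0-based), length,
#'   strand.
#' @export
simulate_footprints <- function(tis_windows, n_reads,
                                frame_weights = rep(1 / 3, 3), seed = 1L,
                                read_length = 29L) {
  if (!is.data.frame(tis_windows) || nrow(tis_windows) == 0)
    abort("`tis_windows` must be a non-empty data frame")
  if (length(frame_weights) != 3 || any(frame_weights < 0) ||
      abs(sum(frame_weights) - 1) > 1e-8)
    abort("`frame_weights` must be 3 non-negative proportions summing to 1")
  if (n_reads == 0)
    return(tibble(chrom = character(), pos = integer(),
                  length = integer(), strand = character()))
  with_sim_seed(seed, {
    w <- sample.int(nrow(tis_windows), n_reads, replace = TRUE)
    f <- sample.int(3, n_reads, replace = TRUE, prob = frame_weights) - 1L
    pos <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      row <- tis_windows[w[i], ]
      cand <- seq(row$start, row$end - 1L)
      cand <- cand[(cand - row$frame_anchor) %% 3L == f[i]]
      pos[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
    }
    tibble(chrom = tis_windows$chrom[w], pos = as.integer(pos),
           length = as.integer(read_length), strand = "+")
  })
}

#' Simulate a toy genome with annotated (optionally duplicated) exons
#'
#' Builds a random-sequence single-chromosome genome containing `n_exons`
#' exons of length `exon_len` separated by random spacers; `n_duplicated` of
#' the exons additionally have an exact copy appended elsewhere on the
#' chromosome. A per-base conservation track is returned with elevated scores
#' over exons. This is the fixture generator for the footprint-mappability
#' and conserved-initiation-site procedures.
#'
#' @param n_exons number of exons (one gene per exon).
#' @param exon_len exon length in bp (must be at least the footprint length
#'   you intend to tile with).
#' @param n_duplicated number of exons to duplicate exactly (<= n_exons).
#' @param seed integer seed.
#' @param spacer_len length of random spacer between features.
#' @return List with `genome` (a [Biostrings::DNAStringSet] with one
#'   chromosome), `exons` (tibble: chrom, start, end, gene_id, score, strand),
#'   `conservation` (tibble: chrom, pos, score), and `duplicated` (gene ids).
#' @export
simulate_toy_genome <- function(n_exons, exon_len, n_duplicated = 0,
                                seed = 1L, spacer_len = 60L) {
  if (n_duplicated > n_exons) abort("n_duplicated must be <= n_exons")
  if (exon_len < 1 || n_exons < 1) abort("n_exons and exon_len must be positive")
  with_sim_seed(seed, {
    rand_seq <- function(k) paste(sample(c("A", "C", "G", "T"), k,
                                         replace = TRUE), collapse = "")
    exon_seq <- vapply(seq_len(n_exons), function(i) rand_seq(exon_len), "")
    pieces <- character(0)
    starts <- integer(n_exons)
    at <- 0L
    for (i in seq_len(n_exons)) {
      sp <- rand_seq(spacer_len)
      pieces <- c(pieces, sp, exon_seq[i])
      at <- at + spacer_len
      starts[i] <- at
      at <- at + exon_len
    }
    dup_idx <- if (n_duplicated > 0) sort(sample.int(n_exons, n_duplicated))
               else integer(0)
    for (i in dup_idx) {
      pieces <- c(pieces, rand_seq(spacer_len), exon_seq[i])
      at <- at + spacer_len + exon_len
    }
    pieces <- c(pieces, rand_seq(spacer_len))
    at <- at + spacer_len
    chrom_seq <- paste(pieces, collapse = "")
    genome <- Biostrings::DNAStringSet(setNames(chrom_seq, "chr1"))

    gene_id <- sprintf("ex%03d", seq_len(n_exons))
    exons <- tibble(chrom = "chr1", start = starts,
                    end = starts + exon_len, gene_id = gene_id,
                    score = 0, strand = "+")
    score <- runif(at, 0.1, 0.5)
    for (i in seq_len(n_exons))
      score[(starts[i] + 1):(starts[i] + exon_len)] <-
        pmin(1, runif(exon_len, 0.9, 1))
    conservation <- tibble(chrom = "chr1", pos = 0:(at - 1L), score = score)
    list(genome = genome, exons = exons, conservation = conservation,
         duplicated = gene_id[dup_idx])
  })
}
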