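# Parametric empirical-Bayes location/scale batch adjustment on log-scale
# matrices. Per gene the data are standardised against a fit that protects
# chosen biological covariates; per-batch location (gamma) and scale (delta^2)
# estimates are shrunk toward parametric priors (normal / inverse-gamma,
# hyperparameters by method of moments across genes) and removed; protected
# effects are restored. Missing values are excluded from estimation and
# preserved in the output.

#' Empirical-Bayes batch adjustment (parametric prior)
#'
#' Removes per-batch location and scale effects from a log-scale expression
#' matrix while protecting biological covariates (by default the species
#' label). With a single batch the input is returned unchanged.
#'
#' @param expr gene x sample log-scale matrix (may contain NA).
#' @param samples sample metadata tibble covering every column.
#' @param batch_key name of the batch column in `samples` (default "batch").
#'   Routing a biological nuisance label (e.g. sex) through this argument
#'   removes that effect instead.
#' @param protect character vector of covariate columns whose effects must be
#'   preserved (default "species"; use NULL to protect nothing beyond the
#'   grand mean).
#' @param conv convergence tolerance of the EB iteration.
#' @return List of class `batch_adjust` with `adjusted` (matrix) and `model`
#'   (per-batch per-gene location/scale estimates before and after shrinkage,
#'   prior hyperparameters, and the protected design). `model` is NULL when
#'   nothing was adjusted.
#' @export
adjust_batch_eb <- function(expr, samples, batch_key = "batch",
                            protect = "species", conv = 1e-8) {
  if (!is.matrix(expr)) abort("`expr` must be a matrix")
  info <- sample_info_for(expr, samples)
  if (!batch_key %in% names(info))
    abort(paste0("no column `", batch_key, "` in samples"))
  batch <- factor(info[[batch_key]])
  if (nlevels(batch) == 1)
    return(structure(list(adjusted = expr, model = NULL),
                     class = "batch_adjust"))
  nb <- table(batch)
  if (any(nb < 2))
    abort(paste0("singleton batch(es): ",
                 paste(names(nb)[nb < 2], collapse = ", ")))

  batch_design <- model.matrix(~ 0 + batch)
  colnames(batch_design) <- levels(batch)
  mod <- NULL
  if (length(protect)) {
    missing_cov <- setdiff(protect, names(info))
    if (length(missing_cov))
      abort(paste0("protected covariate(s) not in samples: ",
                   paste(missing_cov, collapse = ", ")))
    fml <- stats::as.formula(paste("~", paste(protect, collapse = "+")))
    mod <- model.matrix(fml, data = as.data.frame(info))
    mod <- mod[, -1, drop = FALSE]  # intercept lives in the batch columns
  }
  design <- cbind(batch_design, mod)
  if (qr(design)$rank < ncol(design))
    abort("batch is confounded with protected covariates (design not full rank)")

  G <- nrow(expr); n_arr <- ncol(expr)
  n_batch <- nlevels(batch)

  # gene-wise least squares, NA-aware
  has_na <- anyNA(expr)
  if (!has_na) {
    B_hat <- t(solve(crossprod(design), crossprod(design, t(expr))))
  } else {
    B_hat <- matrix(NA_real_, G, ncol(design))
    for (g in seq_len(G)) {
      ok <- !is.na(expr[g, ])
      Xg <- design[ok, , drop = FALSE]
      if (qr(Xg)$rank < ncol(Xg))
        abort(paste0("gene ", rownames(expr)[g],
                     ": insufficient non-missing data to estimate batch effects"))
      B_hat[g, ] <- solve(crossprod(Xg), crossprod(Xg, expr[g, ok]))
    }
  }

  nb_frac <- as.numeric(nb) / n_arr
  grand_mean <- as.vector(B_hat[, seq_len(n_batch), drop = FALSE] %*% nb_frac)
  fitted <- B_hat %*% t(design)
  resid <- expr - fitted
  var_pooled <- rowMeans(resid^2, na.rm = TRUE)
  if (any(var_pooled <= 0))
    abort("gene(s) with zero pooled variance; cannot standardise")
  stand_mean <- matrix(grand_mean, G, n_arr)
  if (!is.null(mod))
    stand_mean <- stand_mean + B_hat[, -seq_len(n_batch), drop = FALSE] %*% t(mod)
  s_data <- (expr - stand_mean) / sqrt(var_pooled)

  batch_cols <- lapply(levels(batch), function(b) which(batch == b))
  names(batch_cols) <- levels(batch)

  gamma_hat <- sapply(batch_cols, function(j)
    rowMeans(s_data[, j, drop = FALSE], na.rm = TRUE))
  delta_hat <- sapply(batch_cols, function(j)
    apply(s_data[, j, drop = FALSE], 1, var, na.rm = TRUE))
  if (any(!is.finite(delta_hat)) || any(delta_hat <= 0, na.rm = TRUE))
    abort("each batch needs >= 2 non-missing values per gene for scale estimation")

  # method-of-moments hyperparameters per batch
  gamma_bar <- colMeans(gamma_hat)
  t2 <- apply(gamma_hat, 2, var)
  a_prior <- vapply(seq_len(n_batch), function(b) {
    m <- mean(delta_hat[, b]); s2 <- var(delta_hat[, b])
    (2 * s2 + m^2) / s2
  }, 0)
  b_prior <- vapply(seq_len(n_batch), function(b) {
    m <- mean(delta_hat[, b]); s2 <- var(delta_hat[, b])
    (m * s2 + m^3) / s2
  }, 0)

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in seq_len(n_batch)) {
    j <- batch_cols[[b]]
    sd_b <- s_data[, j, drop = FALSE]
    n_g <- rowSums(!is.na(sd_b))
    g_old <- gamma_hat[, b]; d_old <- delta_hat[, b]
    for (it in seq_len(1000)) {
      g_new <- (t2[b] * n_g * gamma_hat[, b] + d_old * gamma_bar[b]) /
        (t2[b] * n_g + d_old)
      sum2 <- rowSums((sd_b - g_new)^2, na.rm = TRUE)
      d_new <- (0.5 * sum2 + b_prior[b]) / (n_g / 2 + a_prior[b] - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / d_old, na.rm = TRUE)
      g_old <- g_new; d_old <- d_new
      if (change < conv) break
    }
    gamma_star[, b] <- g_old
    delta_star[, b] <- d_old
  }

  adjusted <- s_data
  for (b in seq_len(n_batch)) {
    j <- batch_cols[[b]]
    adjusted[, j] <- (s_data[, j, drop = FALSE] - gamma_star[, b]) /
      sqrt(delta_star[, b])
  }
  adjusted <- adjusted * sqrt(var_pooled) + stand_mean
  adjusted[is.na(expr)] <- NA_real_
  dimnames(adjusted) <- dimnames(expr)

  model <- list(gamma_hat = gamma_hat, delta_hat = delta_hat,
                gamma_star = gamma_star, delta_star = delta_star,
                gamma_bar = gamma_bar, t2 = t2,
                a_prior = a_prior, b_prior = b_prior,
                batch = batch, design = design, var_pooled = var_pooled)
  structure(list(adjusted = adjusted, model = model), class = "batch_adjust")
}

#' @export
print.batch_adjust <- function(x, ...) {
  if (is.null(x$model)) {
    cat("Batch adjustment: single batch, data returned unchanged\n")
  } else {
    cat("Batch adjustment:", nlevels(x$model$batch), "batches,",
        nrow(x$adjusted), "genes,", ncol(x$adjusted), "samples\n")
  }
  invisible(x)
}

#' @describeIn adjust_batch_eb one-row summary of the shrinkage fit.
#' @param x a `batch_adjust` object.
#' @param ... unused.
#' @export
glance.batch_adjust <- function(x, ...) {
  if (is.null(x$model))
    return(tibble(n_batches = 1L, n_genes = nrow(x$adjusted),
                  mean_abs_gamma = 0, mean_delta = 1))
  tibble(n_batches = nlevels(x$model$batch),
         n_genes = nrow(x$adjusted),
         mean_abs_gamma = mean(abs(x$model$gamma_star)),
         mean_delta = mean(x$model$delta_star))
}
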