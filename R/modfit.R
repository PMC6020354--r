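# Gene-wise weighted least squares with empirical-Bayes variance moderation.
#
# Per gene: weighted LS coefficients, unscaled coefficient SDs (sqrt of the
# diagonal of (X'WX)^-1), residual SD s_g and residual df d_g. Across genes:
# the s_g^2 are modelled as scaled F variates around a prior variance s0^2
# with prior df d0 (estimated by matching the mean and variance of log s_g^2
# to the theoretical moments via the digamma/trigamma system); the posterior
# variance (d0*s0^2 + d_g*s_g^2)/(d0 + d_g) replaces s_g^2 in the t statistic,
# which then has d0 + d_g degrees of freedom.

#' Gene-wise (weighted) linear model fit
#'
#' Fits the same design to every row of `Y` by weighted least squares,
#' skipping missing observations row-wise. Rows whose available observations
#' leave no residual degrees of freedom (or a rank-deficient design) are
#' flagged untestable (NA estimates).
#'
#' @param Y gene x sample response matrix (may contain NA).
#' @param design sample x p design matrix (full rank on complete data).
#' @param weights optional gene x sample matrix of strictly positive weights.
#' @return List of class `genewise_fit`: `coefficients` (genes x p),
#'   `stdev_unscaled` (genes x p), `sigma`, `df_residual` (length-G vectors),
#'   `cov_unscaled` (G x p x p array), `design`.
#' @export
genewise_fit <- function(Y, design, weights = NULL) {
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1, dimnames = list("y1", names(Y)))
  design <- as.matrix(design)
  p <- ncol(design)
  if (nrow(design) != ncol(Y)) abort("`design` must have one row per sample")
  if (qr(design)$rank < p) abort("`design` is rank deficient")
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!identical(dim(weights), dim(Y)))
      abort("`weights` must match the shape of `Y`")
    if (any(weights <= 0 | !is.finite(weights), na.rm = TRUE))
      abort("weights must be strictly positive and finite")
    # only relative weights matter: normalise the global scale so results are
    # invariant to uniform rescaling
    weights <- weights / mean(weights, na.rm = TRUE)
  }
  G <- nrow(Y)
  cn <- colnames(design)
  if (is.null(cn)) cn <- paste0("x", seq_len(p))
  coefs <- sdu <- matrix(NA_real_, G, p, dimnames = list(rownames(Y), cn))
  sigma <- dfres <- rep(NA_real_, G)
  covu <- array(NA_real_, c(G, p, p), dimnames = list(rownames(Y), cn, cn))

  complete <- !anyNA(Y) && is.null(weights)
  if (complete) {
    qrX <- qr(design)
    XtXi <- chol2inv(qr.R(qrX))
    cf <- t(qr.coef(qrX, t(Y)))
    res <- Y - cf %*% t(design)
    dfres[] <- ncol(Y) - p
    sigma <- sqrt(rowSums(res^2) / dfres)
    coefs[] <- cf
    sdu[] <- rep(sqrt(diag(XtXi)), each = G)
    for (g in seq_len(G)) covu[g, , ] <- XtXi
  } else {
    for (g in seq_len(G)) {
      y <- Y[g, ]
      w <- if (is.null(weights)) rep(1, length(y)) else weights[g, ]
      ok <- !is.na(y) & !is.na(w)
      Xg <- design[ok, , drop = FALSE]
      d_g <- sum(ok) - p
      if (d_g < 1 || qr(Xg)$rank < p) next  # untestable
      sw <- sqrt(w[ok])
      xtx <- crossprod(Xg * sw)
      R <- tryCatch(chol(xtx), error = function(e) NULL)
      if (is.null(R)) next
      xtxi <- chol2inv(R)
      beta <- xtxi %*% crossprod(Xg * w[ok], y[ok])
      res <- y[ok] - as.vector(Xg %*% beta)
      coefs[g, ] <- beta
      covu[g, , ] <- xtxi
      sdu[g, ] <- sqrt(diag(xtxi))
      dfres[g] <- d_g
      sigma[g] <- sqrt(sum(w[ok] * res^2) / d_g)
    }
  }
  structure(list(coefficients = coefs, stdev_unscaled = sdu, sigma = sigma,
                 df_residual = dfres, cov_unscaled = covu, design = design),
            class = "genewise_fit")
}

#' @describeIn genewise_fit per-gene, per-term coefficient table.
#' @param x a `genewise_fit`.
#' @param ... unused.
#' @export
tidy.genewise_fit <- function(x, ...) {
  cf <- x$coefficients
  tibble(gene_id = rep(rownames(cf) %||% seq_len(nrow(cf)), ncol(cf)),
         term = rep(colnames(cf), each = nrow(cf)),
         estimate = as.vector(cf),
         stdev_unscaled = as.vector(x$stdev_unscaled),
         sigma = rep(x$sigma, ncol(cf)),
         df_residual = rep(x$df_residual, ncol(cf)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inverse of the trigamma function
#'
#' Newton iteration on `trigamma(y) = x`, used when matching moments of log
#' variances to a scaled F distribution.
#'
#' @param x positive values.
#' @return y with `trigamma(y) = x`.
#' @export
trigamma_inverse <- function(x) {
  out <- x
  pos <- is.finite(x) & x > 0
  out[!pos] <- NaN
  out[is.finite(x) & x > 1e7] <- 1 / sqrt(x[is.finite(x) & x > 1e7])
  out[is.finite(x) & x < 1e-6 & x > 0] <- 1 / x[is.finite(x) & x < 1e-6 & x > 0]
  mid <- pos & x <= 1e7 & x >= 1e-6
  y <- 0.5 + 1 / x[mid]
  for (i in seq_len(50)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x[mid]) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(-dif / y) < 1e-10) break
  }
  out[mid] <- y
  out
}

#' Empirical-Bayes moderation of gene-wise residual variances
#'
#' Estimates the prior df `d0` and prior variance `s0^2` of a scaled-F model
#' for the gene-wise sample variances by moment matching on the log scale,
#' and returns the posterior (moderated) variances
#' `(d0*s0^2 + d_g*s_g^2) / (d0 + d_g)`. If the empirical spread of
#' `log s_g^2` does not exceed its theoretical sampling variance, `d0 = Inf`
#' and every posterior variance equals `s0^2`.
#'
#' @param sigma per-gene residual SDs (genes with NA or zero df are ignored
#'   in estimation but still receive posterior variances).
#' @param df per-gene residual degrees of freedom.
#' @param df_prior optional forced prior df (0 = no moderation, Inf = full
#'   pooling); when supplied, `s0^2` is still estimated from the data.
#' @return List of class `eb_moderation`: `df_prior`, `var_prior`,
#'   `var_post` (per gene), plus the inputs.
#' @export
moderate_variances <- function(sigma, df, df_prior = NULL) {
  s2 <- sigma^2
  ok <- is.finite(s2) & is.finite(df) & df >= 1 & s2 > 0
  if (sum(ok) < 2) abort("too few genes with positive residual variance")
  if (all(s2[is.finite(s2)] == 0)) abort("all residual variances are zero")
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df[ok] / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # spread of log variances no larger than pure sampling noise: infinite
    # prior df, pooled variance as the common value
    d0 <- Inf
    s02 <- mean(s2[ok])
  }
  if (!is.null(df_prior)) d0 <- df_prior
  var_post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    vp <- (d0 * s02 + df * s2) / (d0 + df)
    if (d0 == 0) vp <- s2
    vp
  }
  var_post[!is.finite(var_post)] <- s02
  structure(list(df_prior = d0, var_prior = s02, var_post = var_post,
                 sigma = sigma, df_residual = df),
            class = "eb_moderation")
}

#' @describeIn moderate_variances one-row summary (prior df, prior variance).
#' @param x an `eb_moderation`.
#' @param ... unused.
#' @export
glance.eb_moderation <- function(x, ...) {
  tibble(df_prior = x$df_prior, var_prior = x$var_prior,
         n_genes = length(x$var_post),
         median_var_post = median(x$var_post, na.rm = TRUE))
}

#' Moderated t-test of one coefficient or contrast
#'
#' `t = beta / (sqrt(var_post) * stdev_unscaled)` with `d0 + d_g` degrees of
#' freedom (standard normal when `d0 = Inf`); two-sided p.
#'
#' @param fit a [genewise_fit()].
#' @param moderation an [moderate_variances()] result for `fit`.
#' @param coef coefficient name, or a numeric contrast vector of length p.
#' @return Tibble: gene_id, effect, t_mod, p_nominal, df_total.
#' @export
test_coefficient <- function(fit, moderation, coef) {
  if (is.character(coef)) {
    if (!coef %in% colnames(fit$coefficients))
      abort(paste0("no coefficient `", coef, "` in fit"))
    beta <- fit$coefficients[, coef]
    sdu <- fit$stdev_unscaled[, coef]
  } else {
    cvec <- as.numeric(coef)
    if (length(cvec) != ncol(fit$coefficients))
      abort("contrast length must match the number of coefficients")
    beta <- as.vector(fit$coefficients %*% cvec)
    G <- nrow(fit$coefficients)
    sdu <- vapply(seq_len(G), function(g)
      sqrt(drop(t(cvec) %*% fit$cov_unscaled[g, , ] %*% cvec)), 0)
  }
  d0 <- moderation$df_prior
  se <- sqrt(moderation$var_post) * sdu
  t_mod <- beta / se
  t_mod[which(beta == 0)] <- 0  # exact zero effects get t = 0 even if se = 0
  df_total <- moderation$df_prior + fit$df_residual
  p <- if (is.infinite(d0)) 2 * pnorm(-abs(t_mod))
       else 2 * pt(-abs(t_mod), df = df_total)
  p[which(beta == 0)] <- 1
  tibble(gene_id = rownames(fit$coefficients) %||%
           as.character(seq_along(beta)),
         effect = unname(beta), t_mod = unname(t_mod),
         p_nominal = unname(p), df_total = unname(df_total))
}
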