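# Univariate GBLUP per experiment: REML by eigendecomposition of the
# observed-genotype kinship submatrix with 1-D golden-section search over the
# log variance ratio, BLUPs from the mixed-model equations at the optimum,
# and the constant-prediction averaging strategies used as baselines.

#' Fit a univariate GBLUP model to one experiment
#'
#' Model: `y = mu + g + e`, `g ~ N(0, s2_g K)`, `e ~ N(0, s2_e I)`.  REML is
#' maximised by a one-time eigendecomposition of the observed submatrix of K
#' and golden-section search over `log(s2_g/s2_e)` on \[-10, 10\]
#' (tolerance 1e-8); BLUPs solve the mixed-model equations at the optimum.
#'
#' @param y named numeric vector of phenotypes (names = genotype ids);
#'   `NA`s are dropped.  At least 3 observations required.
#' @param K kinship matrix covering the observed genotypes.
#' @return object of class `"gblup"`: list with `mu`, `g_hat` (named BLUPs),
#'   `sigma2_g`, `sigma2_e`, `h2`, `loglik` (REML), `genotypes`.
#' @export
fit_gblup <- function(y, K) {
  y <- y[!is.na(y)]
  if (length(y) < 3) stop("fit_gblup needs at least 3 observations")
  ids <- names(y)
  if (is.null(ids)) stop("y must be named by genotype id")
  if (!all(ids %in% rownames(K))) stop("kinship does not cover all genotypes")
  Ko <- K[ids, ids]
  n <- length(y)
  if (stats::sd(y) < 1e-12) {
    warning("all phenotypes equal; returning zero genetic variance")
    g <- stats::setNames(rep(0, n), ids)
    return(structure(list(mu = y[[1]], g_hat = g, sigma2_g = 0,
                          sigma2_e = 0, h2 = 0, loglik = NA_real_,
                          genotypes = ids), class = "gblup"))
  }
  eg <- eigen(Ko, symmetric = TRUE)
  d <- pmax(eg$values, 1e-10)
  yt <- crossprod(eg$vectors, y)
  xt <- crossprod(eg$vectors, rep(1, n))
  # REML log-likelihood profile in the ratio lambda = s2_g/s2_e
  reml_ll <- function(loglam) {
    lam <- exp(loglam)
    v <- lam * d + 1                       # V / s2_e
    xvx <- sum(xt^2 / v)
    beta <- sum(xt * yt / v) / xvx
    r <- yt - xt * beta
    ss <- sum(r^2 / v)
    s2e <- ss / (n - 1)
    -0.5 * ((n - 1) * log(s2e) + sum(log(v)) + log(xvx) + (n - 1))
  }
  opt <- stats::optimize(reml_ll, c(-10, 10), maximum = TRUE, tol = 1e-8)
  lam <- exp(opt$maximum)
  v <- lam * d + 1
  beta <- sum(xt * yt / v) / sum(xt^2 / v)
  r <- yt - xt * beta
  s2e <- sum(r^2 / v) / (n - 1)
  s2g <- lam * s2e
  # BLUP: g = s2g K V^-1 (y - mu), in the eigenbasis
  g <- eg$vectors %*% (lam * d / v * r)
  g <- stats::setNames(as.vector(g), ids)
  structure(list(mu = beta, g_hat = g, sigma2_g = s2g, sigma2_e = s2e,
                 h2 = s2g / (s2g + s2e), loglik = opt$objective,
                 genotypes = ids), class = "gblup")
}

#' @export
print.gblup <- function(x, ...) {
  cat(sprintf("GBLUP fit: n = %d, h2 = %.3f (s2_g = %.4g, s2_e = %.4g)\n",
              length(x$g_hat), x$h2, x$sigma2_g, x$sigma2_e))
  invisible(x)
}

#' Predict new genotypes from a GBLUP fit by kinship regression
#'
#' Returns `K_no K_oo^-1 g_hat` (optionally plus the intercept), the
#' conditional-mean prediction of unphenotyped genotypes given the training
#' BLUPs.  A near-singular `K_oo` is solved via its eigendecomposition with
#' eigenvalues floored at 1e-10 (with a warning).
#'
#' @param fit a [fit_gblup] object.
#' @param K_new cross-kinship (new genotypes x training genotypes; columns
#'   matched by name when present) or a full kinship covering both.
#' @param K training kinship (needed to form `K_oo`); defaults to `K_new`
#'   when that is a full square kinship.
#' @param include_mu add the intercept to return phenotype-scale values.
#' @return named numeric vector of predicted genetic values.
#' @export
gblup_predict_new_geno <- function(fit, K_new, K = K_new, include_mu = FALSE) {
  ids <- fit$genotypes
  K_new <- as.matrix(K_new)
  if (!is.null(colnames(K_new)) && all(ids %in% colnames(K_new)))
    K_no <- K_new[, ids, drop = FALSE]
  else if (ncol(K_new) == length(ids)) K_no <- K_new
  else stop("K_new columns must cover the training genotypes")
  Koo <- K[ids, ids]
  eg <- eigen(Koo, symmetric = TRUE)
  if (min(eg$values) < 1e-10)
    warning("near-singular training kinship; eigenvalues floored at 1e-10")
  d <- pmax(eg$values, 1e-10)
  w <- K_no %*% (eg$vectors %*% (t(eg$vectors) / d))
  out <- as.vector(w %*% fit$g_hat)
  if (include_mu) out <- out + fit$mu
  stats::setNames(out, rownames(K_new))
}

#' Constant-prediction strategies for GBLUP in new environments
#'
#' The univariate baseline for new environments: per genotype, average the
#' per-experiment GBLUP predictions across the training experiments in the
#' target's cluster (or across all of them), and assign that vector to every
#' target environment of the cluster.
#'
#' @param per_experiment named list (by training experiment id) of named
#'   numeric prediction vectors; genotypes are aligned by union of names.
#' @param targets character vector of target environment ids.
#' @param clusters optional named character vector mapping experiment ids to
#'   cluster labels (see [constant_prediction]); `NULL` = average all.
#' @return a `"met_prediction"` with one column per target.
#' @export
gblup_new_env_strategy <- function(per_experiment, targets, clusters = NULL) {
  genos <- sort(unique(unlist(lapply(per_experiment, names))))
  E <- sapply(per_experiment, function(v) v[genos])
  rownames(E) <- genos
  pred <- new_met_prediction(E, E * 0, "Ano", "GBLUP")
  constant_prediction(pred, targets, clusters)
}
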