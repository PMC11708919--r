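# Posterior prediction of genetic values for the four old/new genotype x
# old/new environment targets, plus the constant (experiment-average)
# strategy used when a model's predictor side is "O".

new_met_prediction <- function(est, sd, kind, label) {
  structure(list(estimates = est, sd = sd, target_kind = kind,
                 provenance = label), class = "met_prediction")
}

#' @export
print.met_prediction <- function(x, ...) {
  cat(sprintf("Genetic-value predictions (%s, model %s): %d genotypes x %d environments\n",
              x$target_kind, x$provenance, nrow(x$estimates),
              ncol(x$estimates)))
  invisible(x)
}

#' @export
as.matrix.met_prediction <- function(x, ...) x$estimates

# rows of K_new x inverse training kinship, via the context eigendecomposition
# (eigenvalues floored at 1e-10).
cross_kinship_weights <- function(fit, K_new) {
  K_new <- as.matrix(K_new)
  if (!is.null(colnames(K_new))) {
    if (!all(fit$genotypes %in% colnames(K_new)))
      stop("K_new columns must cover all training genotypes")
    K_new <- K_new[, fit$genotypes, drop = FALSE]
  } else if (ncol(K_new) != length(fit$genotypes))
    stop("K_new has wrong number of columns")
  K_new %*% (fit$ctx$Q %*% (t(fit$ctx$Q) / fit$ctx$d))
}

# per-draw loading matrix for new environments from the EC regression:
# Lambda_n = sum over used terms of W_ln A_l  (k x t_new), for draw s.
new_env_loadings <- function(fit, s, Wn_list, rows_list) {
  A <- fit$samples$A[s, , , drop = TRUE]
  if (is.null(dim(A))) A <- matrix(A, dim(fit$samples$A)[2],
                                   dim(fit$samples$A)[3])
  Ln <- 0
  for (i in seq_along(Wn_list))
    Ln <- Ln + Wn_list[[i]] %*% A[rows_list[[i]], , drop = FALSE]
  t(Ln)                                   # k x t_new
}

# resolve which terms contribute to loading prediction and build their new
# designs once.  Terms in the prior but not the predictor contribute zero.
resolve_new_designs <- function(fit, newdata, new_ec) {
  pred <- fit$spec$predictor_terms
  if (identical(pred, "CONSTANT"))
    stop("model predictor side is 'O'; use constant_prediction()")
  use <- c("intercept", intersect(fit$spec$prior_terms, pred))
  n_new <- if (!is.null(newdata)) nrow(newdata)
  else nrow(as.matrix(new_ec[[1]]))
  Wn_list <- list(); rows_list <- list()
  for (nm in use) {
    if (nm == "intercept") {
      Wn <- matrix(1, n_new, 1)
    } else if (!is.null(new_ec) && nm %in% names(new_ec)) {
      Wn <- ec_new_design(fit$ctx$ec, nm, new_ec[[nm]])
    } else {
      Wn <- ec_new_design(fit$ctx$ec, nm, newdata)
    }
    Wn_list[[length(Wn_list) + 1L]] <- Wn
    rows_list[[length(rows_list) + 1L]] <-
      which(fit$ctx$term_names[fit$ctx$term_idx] == nm)
  }
  list(Wn = Wn_list, rows = rows_list, n_new = n_new)
}

summarise_draws <- function(acc, acc2, S) {
  est <- acc / S
  vr <- pmax(acc2 / S - est^2, 0)
  list(est = est, sd = sqrt(vr * S / max(S - 1, 1)))
}

#' Predict genetic values from a fitted MET factor model
#'
#' Four targets are supported, named by genotype/environment novelty:
#' \describe{
#' \item{`"Goo"`}{old genotypes, old (training) environments:
#'   per draw `F Lambda + U_R`, averaged over draws.}
#' \item{`"Ano"`}{new genotypes, old environments: per draw
#'   `(K_no K_oo^-1 U_F) Lambda + K_no K_oo^-1 U_R` (additive values only).}
#' \item{`"Gon"`}{old genotypes, new environments: per draw `F Lambda_n'`
#'   with `Lambda_n` built from the EC regression coefficients of the
#'   model's predictor terms (never from U_R; new environments have no
#'   residual trait).}
#' \item{`"Ann"`}{new genotypes, new environments: `Gon` with `F` replaced by
#'   `K_no K_oo^-1 U_F`, composed per draw.}
#' }
#' All summaries are means over retained draws; `sd` is the draw standard
#' deviation.
#'
#' @param object a fitted [metfa] model.
#' @param what target kind, one of `"Goo"`, `"Ano"`, `"Gon"`, `"Ann"`.
#' @param K_new cross-kinship matrix (new genotypes x training genotypes, or
#'   any kinship whose columns cover the training genotypes); required for
#'   `"Ano"`/`"Ann"`.
#' @param newdata metadata data.frame for the new environments (one row
#'   each), used to build predictor-term designs; required for
#'   `"Gon"`/`"Ann"`.
#' @param new_ec optional named list of raw covariate matrices for
#'   matrix-valued EC terms (rows = new environments); takes precedence over
#'   `newdata` for the named terms.
#' @param ... unused.
#' @return a `"met_prediction"`: list with `estimates`, `sd`, `target_kind`,
#'   `provenance`.
#' @export
predict.metfa <- function(object, what = c("Goo", "Ano", "Gon", "Ann"),
                          K_new = NULL, newdata = NULL, new_ec = NULL, ...) {
  what <- match.arg(what)
  S <- object$n_draws
  sm <- object$samples
  need_kn <- what %in% c("Ano", "Ann")
  need_env <- what %in% c("Gon", "Ann")
  if (need_kn && is.null(K_new)) stop(sprintf("%s requires K_new", what))
  if (need_env && is.null(newdata) && is.null(new_ec))
    stop(sprintf("%s requires newdata and/or new_ec", what))
  M <- if (need_kn) cross_kinship_weights(object, K_new)
  nd <- if (need_env) resolve_new_designs(object, newdata, new_ec)
  acc <- 0; acc2 <- 0
  for (s in seq_len(S)) {
    Fm <- matrix(sm$F[s, , ], dim(sm$F)[2], dim(sm$F)[3])
    Lm <- matrix(sm$Lambda[s, , ], dim(sm$Lambda)[2], dim(sm$Lambda)[3])
    G <- switch(what,
      Goo = Fm %*% Lm + matrix(sm$U_R[s, , ], dim(sm$U_R)[2], dim(sm$U_R)[3]),
      Ano = {
        Um <- matrix(sm$U_F[s, , ], dim(sm$U_F)[2], dim(sm$U_F)[3])
        M %*% (Um %*% Lm) +
          M %*% matrix(sm$U_R[s, , ], dim(sm$U_R)[2], dim(sm$U_R)[3])
      },
      Gon = Fm %*% new_env_loadings(object, s, nd$Wn, nd$rows),
      Ann = {
        Um <- matrix(sm$U_F[s, , ], dim(sm$U_F)[2], dim(sm$U_F)[3])
        (M %*% Um) %*% new_env_loadings(object, s, nd$Wn, nd$rows)
      })
    acc <- acc + G
    acc2 <- acc2 + G^2
  }
  sumr <- summarise_draws(acc, acc2, S)
  rn <- if (need_kn) rownames(K_new) else object$genotypes
  cn <- if (need_env) {
    if (!is.null(newdata) && !is.null(newdata$experiment))
      as.character(newdata$experiment) else NULL
  } else object$experiments
  dimnames(sumr$est) <- dimnames(sumr$sd) <- list(rn, cn)
  new_met_prediction(sumr$est, sumr$sd, what, object$spec$label)
}

#' Constant (experiment-average) predictions for new environments
#'
#' The fall-back used when a model's predictor side is `"O"`: each target
#' environment receives, per genotype, the mean of the per-experiment
#' predictions across the training experiments in its cluster (`clusters =
#' NULL` averages over all training experiments).
#'
#' @param per_experiment a `"met_prediction"` over training experiments
#'   (typically `predict(fit, "Goo")` or `"Ano"`).
#' @param targets character vector of target environment ids.
#' @param clusters optional named character vector mapping experiment ids
#'   (both training and target) to cluster labels; a target whose cluster
#'   contains no training experiment falls back to the overall average with
#'   a warning.
#' @return a `"met_prediction"` with one column per target.
#' @export
constant_prediction <- function(per_experiment, targets, clusters = NULL) {
  E <- per_experiment$estimates
  V <- per_experiment$sd^2
  all_mean <- rowMeans(E)
  all_sd <- sqrt(rowSums(V)) / ncol(E)
  est <- matrix(NA_real_, nrow(E), length(targets),
                dimnames = list(rownames(E), targets))
  sdm <- est
  for (i in seq_along(targets)) {
    cols <- seq_len(ncol(E))
    if (!is.null(clusters)) {
      cl <- clusters[[targets[i]]]
      cols <- which(colnames(E) %in% names(clusters)[clusters == cl])
      if (!length(cols)) {
        warning(sprintf("no training experiments in cluster of '%s'; using all",
                        targets[i]))
        cols <- seq_len(ncol(E))
      }
    }
    est[, i] <- rowMeans(E[, cols, drop = FALSE])
    sdm[, i] <- sqrt(rowSums(V[, cols, drop = FALSE])) / length(cols)
  }
  new_met_prediction(est, sdm, "constant",
                     paste0(per_experiment$provenance, " (constant)"))
}

#' Write predictions to CSV
#'
#' Writes the genotype x environment matrix of estimates and, optionally, a
#' long-format table (genotype, environment, estimate, sd, target_kind,
#' model_label).
#'
#' @param pred a `"met_prediction"`.
#' @param file path for the wide matrix CSV.
#' @param long_file optional path for the long-format CSV.
#' @export
write_predictions <- function(pred, file, long_file = NULL) {
  d <- data.frame(genotype = rownames(pred$estimates), pred$estimates,
                  check.names = FALSE)
  utils::write.csv(d, file, row.names = FALSE)
  if (!is.null(long_file)) {
    long <- data.frame(
      genotype = rep(rownames(pred$estimates), ncol(pred$estimates)),
      environment = rep(colnames(pred$estimates),
                        each = nrow(pred$estimates)),
      estimate = as.vector(pred$estimates),
      sd = as.vector(pred$sd),
      target_kind = pred$target_kind,
      model_label = pred$provenance)
    utils::write.csv(long, long_file, row.names = FALSE)
  }
  invisible(pred)
}
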