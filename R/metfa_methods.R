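# Standard modelling methods for fitted "metfa" objects.

#' @export
print.metfa <- function(x, ...) {
  cat("EC-prior factor-analytic MET model\n")
  cat(sprintf("  model: %s\n", x$spec$label))
  cat(sprintf("  data:  %d genotypes x %d experiments (%.1f%% observed)\n",
              x$ctx$n, x$ctx$t, 100 * mean(x$ctx$Obs)))
  cat(sprintf("  chain: %d iterations (%d retained), k_max = %d, seed = %d\n",
              x$control$n_iter, x$n_draws, x$ctx$k, x$control$seed))
  invisible(x)
}

#' Posterior-mean coefficients of a fitted MET factor model
#'
#' @param object a fitted [metfa] model.
#' @param ... unused.
#' @return list with posterior means: `Lambda` (k x t loadings), `A` (EC
#'   regression coefficients, split per term), `B` (fixed effects), `h2_F`
#'   and `h2_R` (heritabilities), `tau` (factor shrinkage precisions).
#' @export
coef.metfa <- function(object, ...) {
  sm <- object$samples
  A_mean <- apply(sm$A, c(2, 3), mean)
  A_split <- split.data.frame(A_mean,
                              object$ctx$term_names[object$ctx$term_idx])
  list(Lambda = apply(sm$Lambda, c(2, 3), mean),
       A = A_split[unique(object$ctx$term_names[object$ctx$term_idx])],
       B = apply(sm$B, c(2, 3), mean),
       h2_F = colMeans(sm$h2_F), h2_R = colMeans(sm$h2_R),
       tau = colMeans(sm$tau))
}

#' @export
fitted.metfa <- function(object, ...) {
  sm <- object$samples
  acc <- 0
  for (s in seq_len(object$n_draws)) {
    Fm <- matrix(sm$F[s, , ], object$ctx$n, object$ctx$k)
    Lm <- matrix(sm$Lambda[s, , ], object$ctx$k, object$ctx$t)
    acc <- acc + object$ctx$X %*% matrix(sm$B[s, , ], object$ctx$p,
                                         object$ctx$t) +
      Fm %*% Lm + matrix(sm$U_R[s, , ], object$ctx$n, object$ctx$t)
  }
  m <- acc / object$n_draws
  dimnames(m) <- dimnames(object$ctx$Y)
  m
}

#' @export
residuals.metfa <- function(object, ...) {
  r <- object$ctx$Y - fitted(object)
  r[!object$ctx$Obs] <- NA
  r
}

#' @export
logLik.metfa <- function(object, ...) {
  ll <- mean(object$loglik[(object$control$burn_in + 1):object$control$n_iter])
  structure(ll, df = NA, class = "logLik")
}

#' @export
summary.metfa <- function(object, ...) {
  co <- coef(object)
  imp <- factor_importance(object)
  out <- list(spec = object$spec$label,
              n = object$ctx$n, t = object$ctx$t, k = object$ctx$k,
              n_draws = object$n_draws,
              h2_F = co$h2_F, h2_R_mean = mean(co$h2_R),
              importance = imp,
              loglik = mean(object$loglik[(object$control$burn_in + 1):
                                            object$control$n_iter]))
  class(out) <- "summary.metfa"
  out
}

#' @export
print.summary.metfa <- function(x, ...) {
  cat(sprintf("Model %s: %d genotypes, %d experiments, %d factors, %d draws\n",
              x$spec, x$n, x$t, x$k, x$n_draws))
  cat(sprintf("Mean observed-data logLik (post burn-in): %.2f\n", x$loglik))
  cat(sprintf("Mean residual-trait heritability: %.3f\n", x$h2_R_mean))
  cat(sprintf("Active factors (max variance share > 1%%): %d\n",
              attr(x$importance, "n_active")))
  top <- utils::head(x$importance, 5)
  cat("Top factors by sum of squared loadings:\n")
  print(top, row.names = FALSE)
  invisible(x)
}

#' Trace and shrinkage diagnostics plot
#'
#' Two panels: the observed-data log-likelihood trace and the per-factor
#' posterior-mean sum of squared loadings (the shrinkage profile).
#'
#' @param x a fitted [metfa] model.
#' @param ... passed to [graphics::plot].
#' @export
plot.metfa <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$loglik, type = "l", xlab = "iteration",
                 ylab = "log-likelihood", main = "Chain trace", ...)
  graphics::abline(v = x$control$burn_in, lty = 2)
  imp <- factor_importance(x)
  graphics::barplot(imp$sum_sq_loadings, names.arg = imp$factor,
                    xlab = "factor", ylab = expression(Sigma ~ Lambda^2),
                    main = "Shrinkage profile")
  invisible(x)
}

#' Posterior-predictive simulation from a fitted model
#'
#' Draws complete trait matrices from the posterior predictive distribution:
#' for each simulation a retained draw is selected and
#' `XB + F Lambda + U_R + noise` is generated.
#'
#' @param object a fitted [metfa] model.
#' @param nsim number of simulated matrices.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of `nsim` genotype x experiment matrices.
#' @export
simulate.metfa <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sm <- object$samples
  idx <- sample.int(object$n_draws, nsim, replace = TRUE)
  lapply(idx, function(s) {
    mu <- object$ctx$X %*% matrix(sm$B[s, , ], object$ctx$p, object$ctx$t) +
      matrix(sm$F[s, , ], object$ctx$n, object$ctx$k) %*%
      matrix(sm$Lambda[s, , ], object$ctx$k, object$ctx$t) +
      matrix(sm$U_R[s, , ], object$ctx$n, object$ctx$t)
    s2e <- (1 - sm$h2_R[s, ]) * sm$sigma2_R[s, ]
    out <- mu + matrix(stats::rnorm(length(mu)), nrow(mu)) *
      matrix(sqrt(s2e), nrow(mu), ncol(mu), byrow = TRUE)
    dimnames(out) <- dimnames(object$ctx$Y)
    out
  })
}
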