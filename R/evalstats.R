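# Meta-analysis of per-experiment predictive abilities (Hunter-Schmidt
# style, pooled with metafor), paired model comparisons via the normal
# theory of dependent correlations, and loading diagnostics.

#' Meta-analytic mean predictive ability
#'
#' Random-effects pooling of raw per-experiment correlations with
#' Hunter-Schmidt sampling variances `v_i = (1 - rbar^2)^2 / (n_i - 1)`,
#' where `rbar` is the sample-size-weighted mean correlation, and the
#' Hunter-Schmidt between-study variance estimator (floored at 0).  Pooling
#' is done with [metafor::rma].
#'
#' @param table an `"ability_table"` (needs columns `ability` and `n_test`),
#'   or a data.frame with those columns; undefined abilities (`NA`) are
#'   dropped.
#' @return a `"meta_result"`: list with `mean`, `se`, `ci_low`, `ci_high`,
#'   `tau2`, `n_experiments`, `p_value`.
#' @export
meta_mean_ability <- function(table) {
  r <- table$ability; n <- table$n_test
  keep <- !is.na(r) & n >= 2
  r <- r[keep]; n <- n[keep]
  if (length(r) < 1) stop("no defined abilities to pool")
  if (length(r) == 1) {
    warning("single experiment; degenerate meta-analysis")
    return(new_meta_result(r, NA_real_, r, r, 0, 1, NA_real_))
  }
  rbar <- sum(n * r) / sum(n)
  vi <- (1 - rbar^2)^2 / (n - 1)
  fit <- metafor::rma(yi = r, vi = vi, method = "HS")
  new_meta_result(as.numeric(fit$beta), fit$se, fit$ci.lb, fit$ci.ub,
                  max(fit$tau2, 0), length(r), fit$pval)
}

new_meta_result <- function(mean, se, lo, hi, tau2, k, p) {
  structure(list(mean = mean, se = se, ci_low = lo, ci_high = hi,
                 tau2 = tau2, n_experiments = k, p_value = p),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Pooled ability %.4f (se %.4f), 95%% CI [%.4f, %.4f], tau2 %.5f, k = %d\n",
              x$mean, x$se, x$ci_low, x$ci_high, x$tau2, x$n_experiments))
  invisible(x)
}

# sampling variance of the difference of two correlations measured on the
# same sample of size n, with r_ab the correlation between the two
# prediction vectors (r_ab = 0 is the independence fallback).
diff_correlation_var <- function(r_a, r_b, n, r_ab = 0) {
  # cov(r_ya, r_yb) for correlations sharing y (Pearson-Filon / Steiger)
  covr <- (r_ab * (1 - r_a^2 - r_b^2) -
             0.5 * r_a * r_b * (1 - r_a^2 - r_b^2 - r_ab^2)) / (n - 1)
  va <- (1 - r_a^2)^2 / (n - 1)
  vb <- (1 - r_b^2)^2 / (n - 1)
  pmax(va + vb - 2 * covr, 1e-12)
}

#' Paired meta-analytic comparison of two models
#'
#' Per experiment, the difference of the two models' abilities is given a
#' normal-theory standard error for two dependent correlations on the same
#' sample (using the correlation between the two prediction vectors when
#' supplied; independence is the fallback), and the differences are pooled
#' by a sample-size-weighted random-effects meta-analysis.  The p-value
#' tests mean difference = 0 (two-sided).
#'
#' @param table_a,table_b ability tables for the two models over the same
#'   experiments.
#' @param r_ab optional numeric vector (aligned to the common experiments)
#'   of correlations between the two models' prediction vectors.
#' @return a `"meta_result"` for the mean difference (a - b).
#' @export
meta_paired_difference <- function(table_a, table_b, r_ab = NULL) {
  ea <- table_a$experiment; eb <- table_b$experiment
  if (!setequal(ea, eb))
    stop(sprintf("experiment sets differ: %s",
                 paste(union(setdiff(ea, eb), setdiff(eb, ea)),
                       collapse = ", ")))
  common <- sort(intersect(ea, eb))
  ia <- match(common, ea); ib <- match(common, eb)
  r1 <- table_a$ability[ia]; r2 <- table_b$ability[ib]
  n <- pmin(table_a$n_test[ia], table_b$n_test[ib])
  keep <- !is.na(r1) & !is.na(r2) & n > 2
  r1 <- r1[keep]; r2 <- r2[keep]; n <- n[keep]
  rab <- if (is.null(r_ab)) rep(0, length(r1)) else r_ab[keep]
  d <- r1 - r2
  if (all(abs(d) < 1e-14))
    return(new_meta_result(0, 0, 0, 0, 0, length(d), 1))
  vi <- diff_correlation_var(r1, r2, n, rab)
  fit <- metafor::rma(yi = d, vi = vi, weights = n, method = "HS")
  new_meta_result(as.numeric(fit$beta), fit$se, fit$ci.lb, fit$ci.ub,
                  max(fit$tau2, 0), length(d), fit$pval)
}

#' Normal-theory confidence interval for a mean ability
#'
#' `mean +/- z * s / sqrt(n)` with `z` the standard-normal quantile of the
#' requested level (1.96 for 95%).
#'
#' @param mean mean predictive ability.
#' @param s standard deviation of abilities across experiments.
#' @param n number of experiments.
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(low, high)`.
#' @export
normal_ci <- function(mean, s, n, level = 0.95) {
  stopifnot(s >= 0, n >= 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(low = mean - z * s / sqrt(n), high = mean + z * s / sqrt(n))
}

#' Scan factor loadings for associations with experiment covariates
#'
#' Regresses each posterior-mean loading row on each candidate covariate
#' (one-hot for categorical covariates), reporting the overall-F p-value
#' with Bonferroni adjustment across the factors tested per covariate.
#'
#' @param lambda_mean k x t posterior-mean loading matrix (e.g.
#'   `coef(fit)$Lambda`).
#' @param candidates data.frame of per-experiment covariates (t rows),
#'   e.g. latitude, longitude, state, tester.
#' @return data.frame with columns `factor`, `covariate`, `p`, `p_adj`,
#'   `neg_log10_p_adj`, `degenerate`.
#' @export
loading_ec_scan <- function(lambda_mean, candidates) {
  k <- nrow(lambda_mean)
  if (nrow(candidates) != ncol(lambda_mean))
    stop("candidates must have one row per experiment")
  rows <- list()
  for (cv in names(candidates)) {
    x <- candidates[[cv]]
    for (f in seq_len(k)) {
      y <- lambda_mean[f, ]
      if (stats::sd(y) < 1e-12) {
        p <- 1; degen <- TRUE
      } else {
        degen <- FALSE
        fit <- stats::lm(y ~ x0, data = data.frame(y = y, x0 = x))
        fs <- summary(fit)$fstatistic
        p <- if (is.null(fs)) 1
        else as.numeric(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, covariate = cv, p = p,
        p_adj = min(p * k, 1), degenerate = degen,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$neg_log10_p_adj <- -log10(pmax(out$p_adj, .Machine$double.xmin))
  out
}

#' Per-factor importance from squared loadings
#'
#' For each factor: the sum over experiments of its squared posterior-mean
#' loadings, and the per-experiment share `lambda_kj^2 / var(yhat_j)` where
#' `yhat` is the posterior-mean genetic-value prediction.  The attribute
#' `"n_active"` counts factors whose maximum share over experiments exceeds
#' `threshold`.
#'
#' @param fit a fitted [metfa] model.
#' @param threshold variance-share threshold for counting a factor as
#'   active (default 0.01).
#' @return data.frame (`factor`, `sum_sq_loadings`, `max_share`), sorted by
#'   `sum_sq_loadings`, with attribute `"n_active"`.
#' @export
factor_importance <- function(fit, threshold = 0.01) {
  L <- apply(fit$samples$Lambda, c(2, 3), mean)
  yhat <- predict(fit, "Goo")$estimates
  vy <- pmax(apply(yhat, 2, stats::var), 1e-12)
  share <- sweep(L^2, 2, vy, "/")
  out <- data.frame(factor = seq_len(nrow(L)),
                    sum_sq_loadings = rowSums(L^2),
                    max_share = apply(share, 1, max))
  out <- out[order(-out$sum_sq_loadings), , drop = FALSE]
  attr(out, "n_active") <- sum(out$max_share > threshold)
  out
}

#' Human-readable scenario summary
#'
#' Writes a text block per model mirroring the content of a bar plot with
#' meta-analytic means, confidence intervals, and significance stars for the
#' pairwise comparison against a reference model.
#'
#' @param table an `"ability_table"` covering one scenario.
#' @param reference optional reference model label for paired comparisons.
#' @param file optional path; when `NULL` the summary is returned invisibly
#'   as a character vector (and printed).
#' @export
scenario_summary <- function(table, reference = NULL, file = NULL) {
  lines <- sprintf("Scenario %s (%d experiments)",
                   table$scenario[1], length(unique(table$experiment)))
  for (m in unique(table$model)) {
    tb <- table[table$model == m, , drop = FALSE]
    mr <- meta_mean_ability(tb)
    stars <- ""
    if (!is.null(reference) && m != reference) {
      cmp <- meta_paired_difference(tb,
                                    table[table$model == reference, ,
                                          drop = FALSE])
      stars <- if (is.na(cmp$p_value)) ""
      else if (cmp$p_value < 0.001) " ***"
      else if (cmp$p_value < 0.01) " **"
      else if (cmp$p_value < 0.05) " *" else ""
    }
    lines <- c(lines, sprintf("  %-16s %.3f [%.3f, %.3f]%s", m, mr$mean,
                              mr$ci_low, mr$ci_high, stars))
  }
  if (!is.null(file)) writeLines(lines, file) else cat(lines, sep = "\n")
  invisible(lines)
}
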