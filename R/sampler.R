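# Gibbs sampler for the EC-prior factor-analytic MET model.
#
# Level 1:  Y = X B + F Lambda + E,  E_.j = u_Rj + e_Rj
# Level 2:  f_k = u_Fk + e_Fk,  u ~ N(0, s2_g K),  e ~ N(0, s2_e I)
# Loadings: lambda_k. = sum_l W_l a_lk + eps_k
#           a_lk ~ N(0, s2_l / tau_k),  eps_kj ~ N(0, 1/(psi_jk tau_k))
#           psi_jk ~ Ga(nu/2, nu/2),  tau_k = prod_{h<=k} delta_h,
#           delta_1 ~ Ga(alpha1, beta1), delta_h ~ Ga(alpha2, beta2)
#
# Factor traits have total variance fixed at 1 (h2_F partitions it; Lambda
# absorbs scale).  Missing cells are handled by full data augmentation.

#' Sampler configuration
#'
#' @param k_max maximum number of latent factors (the shrinkage prior turns
#'   off unneeded ones); default 50.
#' @param n_iter,burn_in,thin Gibbs iteration controls.
#' @param seed RNG seed; the whole chain is deterministic given it.
#' @param h2_grid_size number of discrete heritability values; h2 is sampled
#'   on the grid \{0, 1/m, ..., (m-1)/m\}.
#' @param nu degrees of freedom of the heavy-tailed local shrinkage on the
#'   loading-regression residuals (psi ~ Ga(nu/2, nu/2)).
#' @param alpha1,beta1,alpha2,beta2 hyperparameters of the multiplicative
#'   gamma increments delta; defaults give E(delta) > 1 so shrinkage
#'   increases with factor index.
#' @param sigma_a,sigma_b inverse-Gamma hyperparameters of the per-EC-term
#'   coefficient variance s2_l.
#' @param sigma_R_a,sigma_R_b inverse-Gamma hyperparameters of the residual-
#'   trait total variances.
#' @param prior_B_var prior variance of fixed effects; `Inf` (default) is the
#'   flat prior, a finite value gives a proper N(0, v) prior (needed e.g. for
#'   prior-recovery diagnostics on data-free chains).
#' @param verbose print the data log-likelihood every 100 iterations.
#' @return a list of class `"metfa_control"`.
#' @export
metfa_control <- function(k_max = 50L, n_iter = 5000L, burn_in = 2500L,
                          thin = 5L, seed = 1L, h2_grid_size = 20L,
                          nu = 3, alpha1 = 2.1, beta1 = 1,
                          alpha2 = 3.1, beta2 = 1,
                          sigma_a = 3, sigma_b = 1,
                          sigma_R_a = 2, sigma_R_b = 1,
                          prior_B_var = Inf, verbose = FALSE) {
  stopifnot(k_max >= 1, burn_in < n_iter, thin >= 1, h2_grid_size >= 2,
            nu > 0, alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0,
            sigma_a > 0, sigma_b > 0, sigma_R_a > 0, sigma_R_b > 0,
            prior_B_var > 0)
  structure(list(k_max = as.integer(k_max), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 h2_grid_size = as.integer(h2_grid_size),
                 nu = nu, alpha1 = alpha1, beta1 = beta1,
                 alpha2 = alpha2, beta2 = beta2,
                 sigma_a = sigma_a, sigma_b = sigma_b,
                 sigma_R_a = sigma_R_a, sigma_R_b = sigma_R_b,
                 prior_B_var = prior_B_var, verbose = verbose),
            class = "metfa_control")
}

rinvgamma1 <- function(n, shape, rate) 1 / stats::rgamma(n, shape, rate = rate)

# Precomputations shared by all Gibbs blocks: kinship eigendecomposition over
# the trait-matrix genotypes, the combined prior-term EC design, and sizes.
metfa_setup <- function(inputs, spec, control) {
  stopifnot(inherits(inputs, "met_inputs"))
  rep_ <- validate_inputs(inputs)
  if (!attr(rep_, "ok"))
    stop(paste("invalid inputs:",
               paste(rep_$message[rep_$severity == "error"], collapse = "; ")))
  tr <- inputs$traits
  n <- nrow(tr$values); t_n <- ncol(tr$values)
  if (control$k_max > min(n, t_n))
    stop(sprintf("k_max = %d exceeds min(n, t) = %d", control$k_max,
                 min(n, t_n)))
  Koo <- inputs$K[rownames(tr$values), rownames(tr$values)]
  eg <- eigen(Koo, symmetric = TRUE)
  if (min(eg$values) < -1e-8)
    stop(sprintf("kinship not PSD: smallest eigenvalue %.3e", min(eg$values)))
  d <- pmax(eg$values, 1e-10)
  prior <- spec$prior_terms
  Ws <- lapply(prior, function(nm) ec_term(inputs$ec, nm)$design)
  W <- do.call(cbind, Ws)
  term_idx <- rep(seq_along(prior), vapply(Ws, ncol, 0L))
  list(Y = tr$values, Obs = tr$observed, meta = tr$meta,
       X = inputs$X, Q = eg$vectors, d = d, Koo = Koo,
       W = W, term_idx = term_idx, term_names = prior,
       n = n, t = t_n, p = ncol(inputs$X), P = ncol(W),
       L = length(prior), k = control$k_max,
       h2_grid = seq(0, 1 - 1 / control$h2_grid_size,
                     by = 1 / control$h2_grid_size),
       control = control, spec = spec, ec = inputs$ec)
}

#' Initialise the sampler state
#'
#' F and Lambda come from a truncated SVD of the column-standardised,
#' mean-imputed trait matrix (components ordered by descending singular
#' value); variance partitions start at 0.5; the shrinkage increments delta
#' are drawn from their priors; unobserved cells start at column means.
#' Deterministic given the seed in `ctx$control`.
#'
#' @param ctx sampler context from the internal setup (a fitted [metfa]
#'   object's `$ctx`, or built internally by [metfa()]).
#' @return a list of class `"metfa_state"` holding all MCMC unknowns.
#' @export
initialize_state <- function(ctx) {
  ctrl <- ctx$control
  n <- ctx$n; t_n <- ctx$t; k <- ctx$k
  Ycur <- ctx$Y
  cm <- ifelse(colSums(ctx$Obs) > 0,
               colMeans(ctx$Y, na.rm = TRUE), 0)
  for (j in seq_len(t_n)) Ycur[!ctx$Obs[, j], j] <- cm[j]
  csd <- apply(Ycur, 2, stats::sd)
  csd[!is.finite(csd) | csd < 1e-10] <- 1
  Ys <- sweep(sweep(Ycur, 2, colMeans(Ycur), "-"), 2, csd, "/")
  sv <- svd(Ys, nu = k, nv = k)
  F_ <- sv$u * sqrt(n)
  Lambda <- (diag(sv$d[seq_len(k)], k, k) / sqrt(n)) %*% t(sv$v)
  Lambda <- sweep(Lambda, 2, csd, "*")
  B <- solve(crossprod(ctx$X), crossprod(ctx$X, Ycur))
  resid <- Ycur - ctx$X %*% B - F_ %*% Lambda
  sigma2_R <- pmax(apply(resid, 2, stats::var) + 1e-4, 1e-6)
  delta <- c(stats::rgamma(1, ctrl$alpha1, rate = ctrl$beta1),
             stats::rgamma(k - 1, ctrl$alpha2, rate = ctrl$beta2))
  structure(list(
    B = B, F = F_, U_F = matrix(0, n, k),
    h2_F = rep(0.5, k), Lambda = Lambda,
    A = matrix(0, ctx$P, k), sigma2_l = rep(ctrl$sigma_b / ctrl$sigma_a, ctx$L),
    Psi = matrix(1, t_n, k), delta = delta, tau = cumprod(delta),
    U_R = matrix(0, n, t_n), h2_R = rep(0.5, t_n), sigma2_R = sigma2_R,
    Ycur = Ycur), class = "metfa_state")
}

# h2 on a grid in the kinship eigenbasis: Rt is Q'R (rotated residuals),
# s2 the per-column total variance (1 for factor traits).  Returns sampled
# grid values and the quadratic form at the sampled h2 (for s2 updates).
sample_h2_grid <- function(Rt, d, grid, s2) {
  nc <- ncol(Rt); ng <- length(grid)
  ll <- matrix(0, ng, nc)
  quad <- matrix(0, ng, nc)
  for (g in seq_len(ng)) {
    v <- grid[g] * d + (1 - grid[g])
    quad[g, ] <- colSums(Rt^2 / v)
    ll[g, ] <- -0.5 * (sum(log(v)) + quad[g, ] / s2)
  }
  ll <- sweep(ll, 2, apply(ll, 2, max), "-")
  pr <- exp(ll)
  pr <- sweep(pr, 2, colSums(pr), "/")
  idx <- vapply(seq_len(nc),
                function(j) sample.int(ng, 1L, prob = pr[, j]), 0L)
  list(h2 = grid[idx], quad = quad[cbind(idx, seq_len(nc))])
}

# Conditional draw of the kinship-structured component in the eigenbasis:
# u~ | r~ per coordinate, with genetic variance h2*s2 and residual (1-h2)*s2.
draw_u_eigen <- function(Q, d, Rt, h2, s2) {
  n <- nrow(Rt)
  gd <- outer(d, h2)                      # n x nc of h2_j * d_i
  denom <- gd + rep(1 - h2, each = n)
  mu <- gd / denom * Rt
  vv <- gd * rep(1 - h2, each = n) / denom * rep(s2, each = n)
  Q %*% (mu + matrix(stats::rnorm(length(mu)), n) * sqrt(pmax(vv, 0)))
}

#' Gibbs block: genetic effects, heritabilities and fixed effects
#'
#' For every factor trait (total variance fixed at 1) and every residual
#' trait, redraws the heritability from its exact conditional on a discrete
#' grid in the kinship eigenbasis, the genetic component from its conditional
#' normal, the residual-trait total variance from its inverse-Gamma
#' conditional, and the fixed-effect column from its conditional normal.
#'
#' @param state a `"metfa_state"`.
#' @param ctx the sampler context.
#' @return the updated state.
#' @export
sample_genetic_effects <- function(state, ctx) {
  ctrl <- ctx$control
  Qt <- t(ctx$Q)
  # factor traits
  Ft <- Qt %*% state$F
  hs <- sample_h2_grid(Ft, ctx$d, ctx$h2_grid, rep(1, ctx$k))
  state$h2_F <- hs$h2
  state$U_F <- draw_u_eigen(ctx$Q, ctx$d, Ft, hs$h2, rep(1, ctx$k))
  state$U_F[, hs$h2 == 0] <- 0
  # residual traits
  R <- state$Ycur - ctx$X %*% state$B - state$F %*% state$Lambda
  Rt <- Qt %*% R
  hr <- sample_h2_grid(Rt, ctx$d, ctx$h2_grid, state$sigma2_R)
  state$h2_R <- hr$h2
  state$sigma2_R <- rinvgamma1(ctx$t, ctrl$sigma_R_a + ctx$n / 2,
                               ctrl$sigma_R_b + hr$quad / 2)
  state$U_R <- draw_u_eigen(ctx$Q, ctx$d, Rt, hr$h2, state$sigma2_R)
  state$U_R[, hr$h2 == 0] <- 0
  # fixed effects, flat (or proper normal) prior
  s2e <- (1 - state$h2_R) * state$sigma2_R
  R2 <- state$Ycur - state$F %*% state$Lambda - state$U_R
  XtX <- crossprod(ctx$X)
  XtR <- crossprod(ctx$X, R2)
  for (j in seq_len(ctx$t)) {
    Pm <- XtX / s2e[j]
    if (is.finite(ctrl$prior_B_var))
      Pm <- Pm + diag(1 / ctrl$prior_B_var, ctx$p)
    U <- chol(Pm)
    mu <- backsolve(U, forwardsolve(t(U), XtR[, j] / s2e[j]))
    state$B[, j] <- mu + backsolve(U, stats::rnorm(ctx$p))
  }
  state
}

#' Gibbs block: latent factor scores
#'
#' Redraws each row of F from its conditional normal given the loadings,
#' residual precisions, and its level-2 prior mean (the corresponding row of
#' U_F) and precision 1/(1 - h2_F).  With full data augmentation all rows
#' share one k x k posterior precision, so a single Cholesky serves the whole
#' update.
#'
#' @inheritParams sample_genetic_effects
#' @return the updated state.
#' @export
sample_factor_scores <- function(state, ctx) {
  R <- state$Ycur - ctx$X %*% state$B - state$U_R
  s2e <- (1 - state$h2_R) * state$sigma2_R
  Dinv <- 1 / s2e
  pf <- 1 / (1 - state$h2_F)
  P <- diag(pf, ctx$k) + state$Lambda %*% (Dinv * t(state$Lambda))
  if (!all(is.finite(P)))
    stop(sprintf("non-finite factor-score precision (factor %d)",
                 which(!is.finite(diag(P)))[1]))
  RHS <- sweep(state$U_F, 2, pf, "*") + R %*% (Dinv * t(state$Lambda))
  U <- chol((P + t(P)) / 2)
  M <- t(backsolve(U, forwardsolve(t(U), t(RHS))))
  state$F <- M + t(backsolve(U, matrix(stats::rnorm(ctx$n * ctx$k),
                                       ctx$k, ctx$n)))
  state
}

#' Gibbs block: factor loadings
#'
#' Redraws each experiment's loading column from its conditional normal given
#' the factor scores, the adjusted trait column (Y - XB - U_R), its residual
#' variance, and the EC-regression prior with mean `sum_l W_l[j,] a_l` and
#' precisions `psi_j. * tau`.
#'
#' @inheritParams sample_genetic_effects
#' @return the updated state.
#' @export
sample_loadings <- function(state, ctx) {
  R <- state$Ycur - ctx$X %*% state$B - state$U_R
  s2e <- (1 - state$h2_R) * state$sigma2_R
  if (any(s2e <= 0))
    stop(sprintf("zero residual variance (experiment %d)",
                 which(s2e <= 0)[1]))
  FtF <- crossprod(state$F)
  FtR <- crossprod(state$F, R)
  Mprior <- ctx$W %*% state$A            # t x k prior means
  for (j in seq_len(ctx$t)) {
    pp <- state$Psi[j, ] * state$tau
    Pm <- FtF / s2e[j]
    diag(Pm) <- diag(Pm) + pp
    U <- chol((Pm + t(Pm)) / 2)
    rhs <- FtR[, j] / s2e[j] + pp * Mprior[j, ]
    mu <- backsolve(U, forwardsolve(t(U), rhs))
    state$Lambda[, j] <- mu + backsolve(U, stats::rnorm(ctx$k))
  }
  state
}

#' Gibbs block: loading regression on ECs and shrinkage parameters
#'
#' For each factor, jointly redraws all EC-term regression coefficients from
#' their conjugate normal given the loading row; then the per-term variances
#' s2_l from their inverse-Gamma conditionals, the local precisions psi from
#' their Gamma conditionals, and the multiplicative-gamma increments delta
#' (with tau recomputed after each).
#'
#' @inheritParams sample_genetic_effects
#' @return the updated state.
#' @export
sample_loading_regression <- function(state, ctx) {
  ctrl <- ctx$control
  k <- ctx$k; t_n <- ctx$t; P_n <- ctx$P
  dl <- 1 / state$sigma2_l[ctx$term_idx]
  for (kk in seq_len(k)) {
    psi <- state$Psi[, kk]
    Pm <- crossprod(ctx$W, psi * ctx$W)
    diag(Pm) <- diag(Pm) + dl
    Pm <- state$tau[kk] * Pm
    rhs <- state$tau[kk] * crossprod(ctx$W, psi * state$Lambda[kk, ])
    U <- tryCatch(chol((Pm + t(Pm)) / 2), error = function(e) NULL)
    if (is.null(U)) {
      diag(Pm) <- diag(Pm) + 1e-10
      U <- chol((Pm + t(Pm)) / 2)   # ridge-jitter retry; chol error propagates
    }
    mu <- backsolve(U, forwardsolve(t(U), rhs))
    state$A[, kk] <- mu + backsolve(U, stats::rnorm(P_n))
  }
  Eps <- state$Lambda - t(ctx$W %*% state$A)       # k x t residuals
  # per-term coefficient variances
  for (l in seq_len(ctx$L)) {
    rows <- ctx$term_idx == l
    ss <- sum(state$tau * colSums(state$A[rows, , drop = FALSE]^2))
    state$sigma2_l[l] <- rinvgamma1(1, ctrl$sigma_a + sum(rows) * k / 2,
                                    ctrl$sigma_b + ss / 2)
  }
  dl <- 1 / state$sigma2_l[ctx$term_idx]
  # local precisions
  rate <- (ctrl$nu + t(Eps^2) * rep(state$tau, each = t_n)) / 2
  state$Psi <- matrix(stats::rgamma(t_n * k, (ctrl$nu + 1) / 2, rate = rate),
                      t_n, k)
  # multiplicative-gamma increments; s_k collects all tau_k-scaled quadratics
  s_k <- rowSums(Eps^2 * t(state$Psi)) + colSums(state$A^2 * dl)
  cnt <- t_n + P_n
  for (h in seq_len(k)) {
    tau_mh <- state$tau / state$delta[h]           # tau with delta_h removed
    ix <- h:k
    shape <- (if (h == 1) ctrl$alpha1 else ctrl$alpha2) +
      cnt * (k - h + 1) / 2
    rate_h <- (if (h == 1) ctrl$beta1 else ctrl$beta2) +
      sum(tau_mh[ix] * s_k[ix]) / 2
    state$delta[h] <- stats::rgamma(1, shape, rate = rate_h)
    state$tau <- cumprod(state$delta)
  }
  state
}

#' Gibbs block: missing-data augmentation
#'
#' Redraws every unobserved cell from its conditional normal
#' N(XB + F Lambda + U_R, s2_eRj); observed cells are never touched.
#'
#' @inheritParams sample_genetic_effects
#' @return the updated state.
#' @export
impute_missing_values <- function(state, ctx) {
  miss <- !ctx$Obs
  if (!any(miss)) return(state)
  mu <- ctx$X %*% state$B + state$F %*% state$Lambda + state$U_R
  s2e <- (1 - state$h2_R) * state$sigma2_R
  sd_mat <- matrix(sqrt(s2e), ctx$n, ctx$t, byrow = TRUE)
  state$Ycur[miss] <- mu[miss] + stats::rnorm(sum(miss)) * sd_mat[miss]
  state
}

metfa_loglik <- function(state, ctx) {
  mu <- ctx$X %*% state$B + state$F %*% state$Lambda + state$U_R
  s2e <- (1 - state$h2_R) * state$sigma2_R
  sd_mat <- matrix(sqrt(s2e), ctx$n, ctx$t, byrow = TRUE)
  sum(stats::dnorm(ctx$Y[ctx$Obs], mu[ctx$Obs], sd_mat[ctx$Obs], log = TRUE))
}

#' Fit the EC-prior factor-analytic MET model
#'
#' Runs the Gibbs sampler: per iteration the five blocks are cycled in fixed
#' order (genetic effects, factor scores, loadings, loading regression,
#' imputation); post-burn-in thinned draws of all quantities needed for
#' prediction are retained.  The chain is deterministic given
#' `control$seed`.
#'
#' @param inputs a [met_inputs] bundle.
#' @param spec model specification: a string parsed by [parse_model_spec()]
#'   against the input's EC terms (default: every term on both sides, or
#'   `"O::O"` if the design has only an intercept), or an already-parsed
#'   `model_spec`.
#' @param control a [metfa_control()].
#' @return an object of class `"metfa"`: list with `samples` (arrays of
#'   retained draws, first index = draw), `loglik` (per-iteration observed-
#'   data log-likelihood), `ctx`, `spec`, `control`, and the training ids.
#' @examples
#' sim <- simulate_met(sim_config(n_lines = 60, t_train = 12, t_test = 4,
#'                                k_true = 2, seed = 1))
#' fit <- metfa(sim$inputs, control = metfa_control(k_max = 4, n_iter = 200,
#'                                                  burn_in = 100, seed = 1))
#' fit
#' @export
metfa <- function(inputs, spec = NULL, control = metfa_control()) {
  known <- setdiff(ec_term_names(inputs$ec), "intercept")
  if (is.null(spec)) {
    spec <- if (length(known))
      paste0(paste(known, collapse = "+"), "::", paste(known, collapse = "+"))
    else "O::O"
  }
  if (!inherits(spec, "model_spec"))
    spec <- parse_model_spec(spec, known)
  ctx <- metfa_setup(inputs, spec, control)
  set.seed(control$seed)
  state <- initialize_state(ctx)
  n_keep <- (control$n_iter - control$burn_in) %/% control$thin
  k <- ctx$k
  samples <- list(
    F = array(NA_real_, c(n_keep, ctx$n, k)),
    U_F = array(NA_real_, c(n_keep, ctx$n, k)),
    Lambda = array(NA_real_, c(n_keep, k, ctx$t)),
    A = array(NA_real_, c(n_keep, ctx$P, k)),
    U_R = array(NA_real_, c(n_keep, ctx$n, ctx$t)),
    B = array(NA_real_, c(n_keep, ctx$p, ctx$t)),
    h2_F = matrix(NA_real_, n_keep, k),
    h2_R = matrix(NA_real_, n_keep, ctx$t),
    sigma2_R = matrix(NA_real_, n_keep, ctx$t),
    sigma2_l = matrix(NA_real_, n_keep, ctx$L),
    tau = matrix(NA_real_, n_keep, k),
    delta = matrix(NA_real_, n_keep, k))
  loglik <- numeric(control$n_iter)
  s <- 0L
  for (it in seq_len(control$n_iter)) {
    state <- tryCatch({
      st <- sample_genetic_effects(state, ctx)
      st <- sample_factor_scores(st, ctx)
      st <- sample_loadings(st, ctx)
      st <- sample_loading_regression(st, ctx)
      impute_missing_values(st, ctx)
    }, error = function(e)
      stop(sprintf("Gibbs error at iteration %d: %s", it, conditionMessage(e)),
           call. = FALSE))
    loglik[it] <- metfa_loglik(state, ctx)
    if (control$verbose && it %% 100 == 0)
      message(sprintf("iter %5d  logLik %.2f", it, loglik[it]))
    if (it > control$burn_in && (it - control$burn_in) %% control$thin == 0) {
      s <- s + 1L
      samples$F[s, , ] <- state$F
      samples$U_F[s, , ] <- state$U_F
      samples$Lambda[s, , ] <- state$Lambda
      samples$A[s, , ] <- state$A
      samples$U_R[s, , ] <- state$U_R
      samples$B[s, , ] <- state$B
      samples$h2_F[s, ] <- state$h2_F
      samples$h2_R[s, ] <- state$h2_R
      samples$sigma2_R[s, ] <- state$sigma2_R
      samples$sigma2_l[s, ] <- state$sigma2_l
      samples$tau[s, ] <- state$tau
      samples$delta[s, ] <- state$delta
    }
  }
  structure(list(samples = samples, loglik = loglik, n_draws = n_keep,
                 ctx = ctx, spec = spec, control = control,
                 genotypes = rownames(ctx$Y), experiments = colnames(ctx$Y),
                 final_state = state),
            class = "metfa")
}

#' Persist retained posterior draws to a directory
#'
#' Writes one CSV per retained parameter (draws flattened row-wise, shapes in
#' the manifest), the per-iteration log-likelihood trace, and a JSON manifest
#' with the configuration and seed.
#'
#' @param fit a fitted [metfa] object.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_metfa_samples <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  shapes <- list()
  for (nm in names(fit$samples)) {
    x <- fit$samples[[nm]]
    shapes[[nm]] <- dim(x)
    utils::write.csv(matrix(x, nrow = dim(x)[1]),
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  utils::write.csv(data.frame(iteration = seq_along(fit$loglik),
                              loglik = fit$loglik),
                   file.path(dir, "loglik.csv"), row.names = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("metfa")),
                   spec = fit$spec$label,
                   control = unclass(fit$control), shapes = shapes,
                   n_draws = fit$n_draws,
                   genotypes = fit$genotypes, experiments = fit$experiments)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
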