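# Block-level correctness of the Gibbs sampler: conjugate closed forms on
# tiny instances, determinism, shrinkage behaviour, and chain-level
# parameter recovery.

test_that("state initialisation is deterministic and SVD-based", {
  inputs <- toy_inputs()
  ctx <- toy_ctx(inputs, k_max = 2, seed = 7)
  set.seed(7); s1 <- initialize_state(ctx)
  set.seed(7); s2 <- initialize_state(ctx)
  expect_identical(s1, s2)

  # rank-1 noiseless matrix: the first factor carries essentially all
  # loading mass after initialisation
  u <- rnorm(12); v <- rnorm(6)
  Y1 <- outer(u, v)
  dimnames(Y1) <- dimnames(inputs$traits$values)
  in1 <- met_inputs(trait_matrix(Y1, inputs$traits$meta), inputs$K,
                    inputs$ec)
  ctx1 <- toy_ctx(in1, k_max = 2)
  st <- initialize_state(ctx1)
  ss <- rowSums(st$Lambda^2)
  expect_gt(ss[1] / sum(ss), 0.99)

  # an all-missing column still initialises to finite loadings
  Y2 <- inputs$traits$values
  Y2[, 3] <- NA
  in2 <- met_inputs(trait_matrix(Y2, inputs$traits$meta), inputs$K,
                    inputs$ec)
  ctx2 <- toy_ctx(in2, k_max = 2)
  expect_true(all(is.finite(initialize_state(ctx2)$Lambda)))

  expect_error(toy_ctx(inputs, k_max = 10), "exceeds min")
})

test_that("factor-score conditional matches the normal-normal closed form", {
  # k = 1, t = 1, lambda = 1, residual var 1, prior mean 0 and var 1, y = 2
  # -> posterior mean 1, variance 0.5
  ctx <- unit_ctx(y = 2)
  st0 <- initialize_state(ctx)
  st0$B[] <- 0; st0$U_R[] <- 0; st0$U_F[] <- 0
  st0$Lambda[] <- 1; st0$h2_F[] <- 0
  st0$h2_R[] <- 0; st0$sigma2_R[] <- 1
  st0$Ycur[] <- 2
  set.seed(1)
  draws <- replicate(1e4, sample_factor_scores(st0, ctx)$F[1, 1])
  expect_lt(abs(mean(draws) - 1), 3 * sd(draws) / sqrt(length(draws)))
  expect_equal(var(draws), 0.5, tolerance = 0.05)

  # all-zero loading row: conditional equals the level-2 prior N(U_F, 1-h2)
  st0$Lambda[] <- 0; st0$U_F[] <- 0.7; st0$h2_F[] <- 0.5
  set.seed(2)
  draws2 <- replicate(1e4, sample_factor_scores(st0, ctx)$F[1, 1])
  expect_lt(abs(mean(draws2) - 0.7), 3 * sd(draws2) / sqrt(length(draws2)))
  expect_equal(var(draws2), 0.5, tolerance = 0.05)
})

test_that("loading conditional matches the normal-normal closed form", {
  # single factor, n = 2, f = (1,1), adjusted y = (1,1), s2_eR = 1,
  # prior N(0, precision 1) -> posterior mean 2/3, precision 3
  K <- diag(2); dimnames(K) <- list(c("g1", "g2"), c("g1", "g2"))
  traits <- trait_matrix(matrix(c(1, 1), 2, 1,
                                dimnames = list(c("g1", "g2"), "e1")))
  inputs <- met_inputs(traits, K)
  ctl <- metfa_control(k_max = 1, n_iter = 10, burn_in = 5)
  ctx <- metfa:::metfa_setup(inputs, parse_model_spec("O::O", character()),
                             ctl)
  st <- initialize_state(ctx)
  st$B[] <- 0; st$U_R[] <- 0; st$F[] <- 1
  st$h2_R[] <- 0; st$sigma2_R[] <- 1
  st$Psi[] <- 1; st$tau[] <- 1; st$delta[] <- 1; st$A[] <- 0
  st$Ycur[] <- 1
  set.seed(3)
  draws <- replicate(1e4, sample_loadings(st, ctx)$Lambda[1, 1])
  expect_lt(abs(mean(draws) - 2 / 3), 3 * sd(draws) / sqrt(length(draws)))
  expect_equal(var(draws), 1 / 3, tolerance = 0.03)

  # F = 0: conditional equals the EC-regression prior N(W a, 1/(psi tau))
  st$F[] <- 0; st$A[] <- 0.4
  set.seed(4)
  draws2 <- replicate(1e4, sample_loadings(st, ctx)$Lambda[1, 1])
  expect_lt(abs(mean(draws2) - 0.4), 3 * sd(draws2) / sqrt(length(draws2)))
  expect_equal(var(draws2), 1, tolerance = 0.05)
})

test_that("loading-regression block matches its conjugate closed forms", {
  # two experiments, one factor, intercept-only EC term
  K <- diag(2); dimnames(K) <- list(c("g1", "g2"), c("g1", "g2"))
  traits <- trait_matrix(matrix(rnorm(4), 2, 2,
                                dimnames = list(c("g1", "g2"),
                                                c("e1", "e2"))))
  inputs <- met_inputs(traits, K)
  ctl <- metfa_control(k_max = 1, n_iter = 10, burn_in = 5)
  ctx <- metfa:::metfa_setup(inputs, parse_model_spec("O::O", character()),
                             ctl)
  st <- initialize_state(ctx)
  st$Lambda[] <- 1                        # lambda = (1, 1)
  st$Psi[] <- 1; st$tau[] <- 1; st$delta[] <- 1; st$sigma2_l[] <- 1
  # coefficient conditional: mean 2/3, precision 3 (checked by moments)
  set.seed(5)
  a_draws <- replicate(1e4, sample_loading_regression(st, ctx)$A[1, 1])
  expect_lt(abs(mean(a_draws) - 2 / 3),
            3 * sd(a_draws) / sqrt(length(a_draws)))
  expect_equal(var(a_draws), 1 / 3, tolerance = 0.03)

  # psi conditional at eps ~ 0 (huge entering psi pins the coefficient to
  # the least-squares fit, so the regression residual vanishes):
  # Gamma((nu+1)/2, nu/2) = Gamma(2, 1.5) for nu = 3 -> mean 4/3
  st2 <- st; st2$Psi[] <- 1e8
  set.seed(6)
  out <- replicate(1e4, {
    r <- sample_loading_regression(st2, ctx)
    c(r$Psi[1, 1], r$delta[1])
  })
  psi <- out[1, ]
  expect_lt(abs(mean(psi) - 4 / 3), 3 * sd(psi) / sqrt(length(psi)))
  expect_equal(var(psi), 2 / 1.5^2, tolerance = 0.05)

  # delta_1 conditional when residuals and coefficients vanish
  # (lambda = 0): rate collapses to beta1, shape keeps its Gaussian count
  # alpha1 + (t + P)/2 -> Ga(2.1 + 1.5, 1)
  st3 <- st; st3$Lambda[] <- 0; st3$Psi[] <- 1e8
  set.seed(7)
  d_draws <- replicate(1e4, sample_loading_regression(st3, ctx)$delta[1])
  expect_lt(abs(mean(d_draws) - 3.6), 3 * sd(d_draws) / sqrt(length(d_draws)))
  expect_equal(var(d_draws), 3.6, tolerance = 0.2)
})

test_that("genetic-effect conditionals shrink and detect heritability", {
  # K = I with equal variance components: BLUP mean is y/2, var s2/4... no:
  # var = h2(1-h2)/(h2 d + 1-h2) * s2 = 0.25
  y <- c(2, -1, 0.5)
  set.seed(8)
  draws <- replicate(1e4,
    metfa:::draw_u_eigen(diag(3), rep(1, 3), matrix(y, 3, 1), 0.5, 1))
  dm <- matrix(draws, 3)
  expect_equal(rowMeans(dm), y / 2, tolerance = 4 * sqrt(0.25 / 1e4) * 3)
  expect_equal(var(dm[1, ]), 0.25, tolerance = 0.02)

  # h2 grid: data simulated with h2 = 0 concentrates mass at low h2
  set.seed(9)
  K <- simulate_kinship(500, 50)
  eg <- eigen(K, symmetric = TRUE)
  f <- rnorm(500)                         # pure noise: h2 = 0
  Ft <- crossprod(eg$vectors, f)
  grid <- seq(0, 0.95, by = 0.05)
  hits <- replicate(400, metfa:::sample_h2_grid(matrix(Ft, ncol = 1),
                                                pmax(eg$values, 1e-10),
                                                grid, 1)$h2)
  expect_gt(mean(hits <= 0.1), 0.9)
})

test_that("imputation draws centre on the linear predictor and never touch observed cells", {
  inputs <- toy_inputs(missing = 0.4, seed = 13)
  ctx <- toy_ctx(inputs, k_max = 2)
  st <- initialize_state(ctx)
  miss <- !ctx$Obs
  mu <- ctx$X %*% st$B + st$F %*% st$Lambda + st$U_R
  set.seed(10)
  acc <- 0
  for (i in 1:2000) acc <- acc + impute_missing_values(st, ctx)$Ycur
  imp_mean <- (acc / 2000)[miss]
  s2e <- (1 - st$h2_R) * st$sigma2_R
  sdm <- matrix(sqrt(s2e), ctx$n, ctx$t, byrow = TRUE)[miss]
  expect_true(all(abs(imp_mean - mu[miss]) < 4 * sdm / sqrt(2000)))
  # observed cells identical before and after
  st2 <- impute_missing_values(st, ctx)
  expect_identical(st2$Ycur[ctx$Obs], st$Ycur[ctx$Obs])
  # vanishing residual variance pins the draw to the conditional mean
  st$sigma2_R[] <- 1e-12
  st3 <- impute_missing_values(st, ctx)
  expect_equal(st3$Ycur[miss], mu[miss], tolerance = 1e-4)
})

test_that("the chain is seed-deterministic and conserves observed cells", {
  inputs <- toy_inputs(missing = 0.2, seed = 3)
  ctl <- metfa_control(k_max = 2, n_iter = 60, burn_in = 30, thin = 2,
                       seed = 5)
  f1 <- metfa(inputs, "S+T::S+T", ctl)
  f2 <- metfa(inputs, "S+T::S+T", ctl)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$loglik, f2$loglik)
  obs <- inputs$traits$observed
  expect_identical(f1$final_state$Ycur[obs], inputs$traits$values[obs])
  expect_equal(f1$n_draws, 15)
})

test_that("the log-likelihood is invariant under factor sign flips", {
  inputs <- toy_inputs(seed = 21)
  ctl <- metfa_control(k_max = 3, n_iter = 40, burn_in = 20, seed = 2)
  fit <- metfa(inputs, "S+T::S+T", ctl)
  st <- fit$final_state
  ll0 <- metfa:::metfa_loglik(st, fit$ctx)
  for (h in 1:3) {
    st2 <- st
    st2$F[, h] <- -st2$F[, h]
    st2$U_F[, h] <- -st2$U_F[, h]
    st2$Lambda[h, ] <- -st2$Lambda[h, ]
    st2$A[, h] <- -st2$A[, h]
    expect_identical(metfa:::metfa_loglik(st2, fit$ctx), ll0)
  }
})

test_that("the shrinkage prior concentrates loading mass on the true factors", {
  sim <- simulate_met(sim_config(n_lines = 80, t_train = 16, t_test = 4,
                                 k_true = 3, z_cols = 20,
                                 main_effect_prop = 0.3,
                                 unpredictable_prop = 0.3, seed = 17))
  fit <- metfa(sim$inputs, control = metfa_control(k_max = 8, n_iter = 400,
                                                   burn_in = 200, seed = 4))
  ss <- rowSums(apply(fit$samples$Lambda, c(2, 3), mean)^2)
  top5 <- sum(sort(ss, decreasing = TRUE)[1:5])
  expect_gt(top5 / sum(ss), 0.95)
})

test_that("posterior-mean genetic values recover the simulated truth", {
  sim <- recovery_fixture()
  fit <- metfa(sim$inputs, control = metfa_control(k_max = 4, n_iter = 500,
                                                   burn_in = 250, seed = 6))
  g <- predict(fit, "Goo")$estimates
  truth <- sim$truth$G[, fit$experiments]
  expect_gt(cor(as.vector(g), as.vector(truth)), 0.9)
})

test_that("a data-free chain with proper priors recovers the delta_1 prior", {
  # Geweke-style check: with every cell missing the Gibbs chain targets the
  # joint prior, so delta_1 draws must match Ga(alpha1, beta1)
  K <- simulate_kinship(4, 2, seed = 30)
  Y <- matrix(NA_real_, 4, 3,
              dimnames = list(rownames(K), paste0("e", 1:3)))
  traits <- suppressWarnings(trait_matrix(Y))
  inputs <- met_inputs(traits, K)
  ctl <- metfa_control(k_max = 2, n_iter = 12000, burn_in = 2000, thin = 2,
                       seed = 9, prior_B_var = 1)
  fit <- metfa(inputs, "O::O", ctl)
  d1 <- fit$samples$delta[, 1]
  prior_mean <- ctl$alpha1 / ctl$beta1
  prior_var <- ctl$alpha1 / ctl$beta1^2
  expect_lt(abs(mean(d1) - prior_mean), 3 * batch_se(d1))
  expect_lt(abs(mean(d1^2) - (prior_var + prior_mean^2)),
            3 * batch_se(d1^2))
})
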