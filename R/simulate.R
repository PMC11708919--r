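# Simulation generator for the MET factor model: random kinship, latent
# factor G x E structure with predictable (main-effect + environmental
# gradient) and unpredictable components, three EC exposure modes, and
# uniform missingness.  Doubles as the fixture generator of the test suite.

#' Simulation configuration
#'
#' Defaults are the evaluation study conditions: 500 lines in 500
#' environments (400 training, 100 test), 10 latent factors, heritability
#' 0.8 for every factor and residual trait, factors explaining 80% of
#' phenotypic variance on average, a kinship built from 50 random marker-
#' like columns.  The three loading components share the loading variance:
#' `main_effect_prop` goes to the constant first row, `unpredictable_prop`
#' jointly to rows 3..k_true, the remainder to the environmental-gradient
#' second row.
#'
#' @param n_lines,t_train,t_test,k_true,z_cols problem sizes.
#' @param h2 per-column heritability of factor and residual traits.
#' @param factor_share average proportion of phenotypic variance explained
#'   by the factor term.
#' @param main_effect_prop,unpredictable_prop loading-variance shares (their
#'   sum must be <= 1); with `k_true < 3` the unpredictable share must be 0.
#' @param missing_prop proportion of cells set to missing.
#' @param ec_mode `"categorical"`, `"univariate"` or `"multivariate"`.
#' @param n_replicates replicate count for grid runs.
#' @param seed RNG seed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_lines = 500L, t_train = 400L, t_test = 100L,
                       k_true = 10L, z_cols = 50L, h2 = 0.8,
                       factor_share = 0.8, main_effect_prop = 0.25,
                       unpredictable_prop = 0.4, missing_prop = 0,
                       ec_mode = c("univariate", "categorical",
                                   "multivariate"),
                       n_replicates = 10L, seed = 1L) {
  ec_mode <- match.arg(ec_mode)
  stopifnot(main_effect_prop >= 0, unpredictable_prop >= 0,
            main_effect_prop + unpredictable_prop <= 1,
            missing_prop >= 0, missing_prop < 1,
            h2 >= 0, h2 <= 1, factor_share > 0, factor_share < 1,
            k_true >= 1, n_lines > z_cols, z_cols >= 1)
  if (k_true < 3 && unpredictable_prop > 0)
    stop("unpredictable_prop > 0 requires k_true >= 3")
  structure(list(n_lines = as.integer(n_lines),
                 t_train = as.integer(t_train), t_test = as.integer(t_test),
                 k_true = as.integer(k_true), z_cols = as.integer(z_cols),
                 h2 = h2, factor_share = factor_share,
                 main_effect_prop = main_effect_prop,
                 unpredictable_prop = unpredictable_prop,
                 missing_prop = missing_prop, ec_mode = ec_mode,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a random genomic relationship matrix
#'
#' `K = Z Z' / 100 + 0.5 I` with `Z` an iid standard-normal n x z_cols
#' matrix: z_cols large eigenvalues above the 0.5 baseline and n - z_cols
#' eigenvalues equal to 0.5.
#'
#' @param n number of lines.
#' @param z_cols number of random columns (default 50).
#' @param seed optional seed (`NULL` continues the current RNG stream).
#' @return n x n kinship matrix with ids `g1..gn`.
#' @export
simulate_kinship <- function(n, z_cols = 50L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n > z_cols, z_cols >= 1)
  Z <- matrix(stats::rnorm(n * z_cols), n, z_cols)
  K <- tcrossprod(Z) / 100 + diag(0.5, n)
  ids <- paste0("g", seq_len(n))
  dimnames(K) <- list(ids, ids)
  K
}

#' Simulate the environmental structure driving the gradient factor
#'
#' Three EC exposure modes: `"categorical"` assigns the training
#' environments to 10 groups with standard-normal group values and draws the
#' test environments half from group 1 and half from a new group 11 absent
#' from training (only group identities are exposed as ECs);
#' `"univariate"` draws an independent standard-normal value per environment
#' and exposes it directly; `"multivariate"` draws a 10-column standard-
#' normal matrix W per environment and samples the gradient from
#' `MVN(0, WW'/20 + 0.5 I)` so that about half its variance is explainable
#' from W, which is exposed.
#'
#' @param mode EC mode.
#' @param t_train,t_test environment counts.
#' @param seed optional seed.
#' @return list with `gradient` (length t_train + t_test), `groups`
#'   (character or `NULL`), `W` (matrix or `NULL`), and `ec_value`: the raw
#'   exposed covariate (group labels, the gradient itself, or W).
#' @export
simulate_environment_structure <- function(mode = c("categorical",
                                                    "univariate",
                                                    "multivariate"),
                                           t_train = 400L, t_test = 100L,
                                           seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  t_all <- t_train + t_test
  if (mode == "categorical") {
    if (t_test != 100L)
      warning("categorical mode: test environments split half group 1, half new group")
    n1 <- ceiling(t_test / 2)
    g_train <- rep(seq_len(10L), length.out = t_train)
    groups <- c(paste0("grp", g_train),
                rep("grp1", n1), rep("grp11", t_test - n1))
    vals <- stats::setNames(stats::rnorm(11), paste0("grp", 1:11))
    list(gradient = as.vector(vals[groups]), groups = groups, W = NULL,
         ec_value = groups)
  } else if (mode == "univariate") {
    g <- stats::rnorm(t_all)
    list(gradient = g, groups = NULL, W = NULL,
         ec_value = matrix(g, ncol = 1, dimnames = list(NULL, "W1")))
  } else {
    W <- matrix(stats::rnorm(t_all * 10L), t_all, 10L,
                dimnames = list(NULL, paste0("W", 1:10)))
    g <- as.vector(W %*% stats::rnorm(10L) / sqrt(20) +
                     sqrt(0.5) * stats::rnorm(t_all))
    list(gradient = g, groups = NULL, W = W, ec_value = W)
  }
}

#' Simulate a multi-environment trial under the generative factor model
#'
#' Loading construction: row 1 of Lambda is a constant (all-environment
#' positive covariance), row 2 the environmental gradient, rows 3..k_true
#' iid unpredictable loadings; the three parts are weighted so their shares
#' of the average per-environment loading sum of squares equal
#' `main_effect_prop`, `1 - main - unpredictable`, and
#' `unpredictable_prop`.  Factor scores and residual traits each split a
#' kinship-structured genetic component and an iid component at heritability
#' `h2`; the residual matrix is rescaled by one global scalar so the
#' across-environment average of `var(F Lambda col)/var(Y col)` equals
#' `factor_share`.  Finally `missing_prop` of all cells is masked uniformly
#' at random (an exact count).
#'
#' @param config a [sim_config].
#' @return list with `inputs` (a [met_inputs] over the training
#'   environments, EC term `"W"` exposed per the mode), `truth` (Lambda, F,
#'   genetic components, the complete phenotype matrix, true genetic values,
#'   gradient/groups/W, per-column realized heritabilities and factor
#'   shares, test-environment metadata and raw ECs), and `config`.
#' @export
simulate_met <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_lines; t_all <- config$t_train + config$t_test
  k <- config$k_true
  K <- simulate_kinship(n, config$z_cols)
  env <- simulate_environment_structure(config$ec_mode, config$t_train,
                                        config$t_test)
  # --- loadings -----------------------------------------------------------
  main <- config$main_effect_prop
  unpred <- if (k >= 3) config$unpredictable_prop else 0
  grad_share <- 1 - main - unpred
  Lambda <- matrix(0, k, t_all)
  Lambda[1, ] <- sqrt(main)
  g <- env$gradient
  if (k >= 2)
    Lambda[2, ] <- g / sqrt(mean(g^2)) * sqrt(grad_share)
  if (k >= 3) {
    R <- matrix(stats::rnorm((k - 2) * t_all), k - 2, t_all)
    if (unpred > 0)
      R <- R * sqrt(unpred / mean(colSums(R^2)))
    else R <- R * 0
    Lambda[3:k, ] <- R
  }
  # --- factor scores and residual traits ---------------------------------
  Lc <- t(chol(K + diag(1e-8, n)))
  h2 <- config$h2
  U_F <- sqrt(h2) * (Lc %*% matrix(stats::rnorm(n * k), n, k))
  E_F <- sqrt(1 - h2) * matrix(stats::rnorm(n * k), n, k)
  F_ <- U_F + E_F
  U_R0 <- sqrt(h2) * (Lc %*% matrix(stats::rnorm(n * t_all), n, t_all))
  E_R0 <- sqrt(1 - h2) * matrix(stats::rnorm(n * t_all), n, t_all)
  E0 <- U_R0 + E_R0
  FL <- F_ %*% Lambda
  vF <- apply(FL, 2, stats::var)
  vE <- apply(E0, 2, stats::var)
  cFE <- vapply(seq_len(t_all),
                function(j) stats::cov(FL[, j], E0[, j]), 0)
  fs <- config$factor_share
  ratio_gap <- function(s)
    mean(vF / (vF + s^2 * vE + 2 * s * cFE)) - fs
  s_E <- stats::uniroot(ratio_gap, c(1e-8, 1e3), tol = 1e-10)$root
  E <- s_E * E0
  Y <- FL + E
  # --- ids, metadata, masking --------------------------------------------
  gids <- rownames(K)
  eids <- sprintf("env%03d", seq_len(t_all))
  dimnames(Y) <- list(gids, eids)
  dimnames(FL) <- dimnames(E) <- list(gids, eids)
  rownames(F_) <- rownames(U_F) <- gids
  colnames(Lambda) <- eids
  meta_all <- data.frame(
    experiment = eids, location = eids,
    year = 2014L + (seq_len(t_all) - 1L) %% 8L,
    state = if (!is.null(env$groups)) env$groups
    else paste0("S", 1L + (seq_len(t_all) - 1L) %% 5L),
    tester = paste0("T", 1L + (seq_len(t_all) - 1L) %% 4L),
    stringsAsFactors = FALSE)
  mask <- matrix(FALSE, n, t_all)
  n_miss <- round(config$missing_prop * n * t_all)
  if (n_miss > 0)
    mask[sample.int(n * t_all, n_miss)] <- TRUE
  Y_obs <- Y
  Y_obs[mask] <- NA
  # --- training inputs ----------------------------------------------------
  tr_idx <- seq_len(config$t_train)
  meta_tr <- meta_all[tr_idx, , drop = FALSE]
  ec_tr <- if (config$ec_mode == "categorical")
    ec_design_set(meta_tr, list(W = "state"))
  else ec_design_set(meta_tr,
                     list(W = env$ec_value[tr_idx, , drop = FALSE]))
  traits <- trait_matrix(Y_obs[, tr_idx, drop = FALSE], meta_tr)
  inputs <- met_inputs(traits, K, ec_tr)
  # --- truth --------------------------------------------------------------
  U_R <- s_E * U_R0
  dimnames(U_R) <- list(gids, eids)
  h2_real <- c(apply(U_F, 2, stats::var) / apply(F_, 2, stats::var),
               apply(U_R0, 2, stats::var) / apply(E0, 2, stats::var))
  truth <- list(Lambda = Lambda, F = F_, U_F = U_F, U_R = U_R, E = E,
                Y_full = Y, G = FL + U_R,
                gradient = env$gradient, groups = env$groups, W = env$W,
                sigma_E = s_E,
                realized_h2 = h2_real,
                realized_factor_share = vF / (vF + s_E^2 * vE + 2 * s_E * cFE),
                meta_all = meta_all,
                test_meta = meta_all[-tr_idx, , drop = FALSE],
                test_ec = if (config$ec_mode == "categorical") NULL
                else env$ec_value[-tr_idx, , drop = FALSE],
                mask = mask)
  list(inputs = inputs, truth = truth, config = config)
}

# mean per-environment predictive ability of a prediction matrix against
# phenotypes, over the given genotype and environment index sets.
sim_goal_ability <- function(pred, Y, genos, envs) {
  rs <- vapply(envs, function(j)
    predictive_ability(Y[genos, j], pred[genos, j]), 0)
  mean(rs, na.rm = TRUE)
}

#' Run the simulation study grid
#'
#' For each replicate of each configuration: simulates a dataset, holds out
#' `new_geno_prop` of the lines as new genotypes, fits the EC-prior factor
#' model with `k_fit` factors (EC term `W` as prior and predictor) on the
#' training lines x training environments, fits per-environment GBLUP
#' baselines, and scores the requested prediction goals as mean
#' per-environment correlations with the simulated phenotypes.
#'
#' Goals: `CV1` (new genotypes, training environments), `CV2` (old
#' genotypes at masked cells; requires `missing_prop > 0`), `NewTrial`
#' (test environments from group 1; categorical mode), `NewState` (test
#' environments from the unseen group 11; categorical mode), `NewEnv` (test
#' environments; quantitative modes), and their `NewGeno` composites.
#' Incompatible goal/mode combinations are skipped with a log attribute.
#'
#' @param configs a [sim_config] or list of them.
#' @param goals character vector of goals (default all compatible).
#' @param k_fit factors used by the fitted model (default 15).
#' @param new_geno_prop proportion of lines held out as new genotypes.
#' @param control sampler control (default scaled to the problem).
#' @param models which models to run: `"metfa"`, `"GBLUP"` or both.
#' @return data.frame (`config`, `replicate`, `goal`, `model`, `ability`,
#'   `n_envs`), with a `"skipped"` attribute.
#' @export
run_sim_study <- function(configs, goals = c("CV1", "CV2", "NewTrial",
                                             "NewState", "NewEnv",
                                             "NewGenoNewTrial",
                                             "NewGenoNewState",
                                             "NewGenoNewEnv"),
                          k_fit = 15L, new_geno_prop = 0.2,
                          control = NULL, models = c("metfa", "GBLUP")) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  goals <- match.arg(goals, several.ok = TRUE)
  rows <- list(); skipped <- character()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    for (r in seq_len(cfg$n_replicates)) {
      cfg_r <- cfg; cfg_r$seed <- cfg$seed + r
      sim <- simulate_met(cfg_r)
      Y <- sim$truth$Y_full
      n <- cfg$n_lines
      set.seed(cfg_r$seed + 10000L)
      new_g <- sort(sample.int(n, round(new_geno_prop * n)))
      old_g <- setdiff(seq_len(n), new_g)
      gids <- rownames(Y)
      tr_envs <- seq_len(cfg$t_train)
      te_envs <- setdiff(seq_len(ncol(Y)), tr_envs)
      # training inputs restricted to old lines
      vals <- sim$inputs$traits$values[old_g, , drop = FALSE]
      tri <- met_inputs(trait_matrix(vals, sim$inputs$traits$meta),
                        sim$inputs$K, sim$inputs$ec)
      goal_envs <- function(goal) {
        if (goal %in% c("NewTrial", "NewGenoNewTrial")) {
          if (cfg$ec_mode != "categorical") return(NULL)
          te_envs[sim$truth$groups[te_envs] == "grp1"]
        } else if (goal %in% c("NewState", "NewGenoNewState")) {
          if (cfg$ec_mode != "categorical") return(NULL)
          te_envs[sim$truth$groups[te_envs] == "grp11"]
        } else if (goal %in% c("NewEnv", "NewGenoNewEnv")) {
          if (cfg$ec_mode == "categorical") return(NULL)
          te_envs
        } else te_envs
      }
      preds <- list()
      if ("metfa" %in% models) {
        ctl <- control
        if (is.null(ctl))
          ctl <- metfa_control(k_max = k_fit, n_iter = 600, burn_in = 300,
                               thin = 3, seed = cfg_r$seed)
        ctl$k_max <- as.integer(min(k_fit, nrow(vals) - 1, ncol(vals) - 1))
        fit <- metfa(tri, "W::W", ctl)
        K_no <- sim$inputs$K[gids[new_g], , drop = FALSE]
        new_env_args <- function(envs) {
          nm <- sim$truth$meta_all[envs, , drop = FALSE]
          ne <- if (cfg$ec_mode == "categorical") NULL
          else list(W = sim$truth$test_ec[match(envs, te_envs), ,
                                          drop = FALSE])
          list(newdata = nm, new_ec = ne)
        }
        preds$metfa <- function(goal, envs) {
          ga <- new_env_args(envs)
          full <- matrix(NA_real_, n, ncol(Y), dimnames = dimnames(Y))
          if (goal == "CV1") {
            pr <- predict(fit, "Ano", K_new = K_no)
            full[new_g, tr_envs] <- pr$estimates
          } else if (goal == "CV2") {
            pr <- predict(fit, "Goo")
            full[old_g, tr_envs] <- pr$estimates
          } else if (grepl("^NewGeno", goal)) {
            pr <- suppressWarnings(predict(fit, "Ann", K_new = K_no,
                                           newdata = ga$newdata,
                                           new_ec = ga$new_ec))
            full[new_g, envs] <- pr$estimates
          } else {
            pr <- suppressWarnings(predict(fit, "Gon", newdata = ga$newdata,
                                           new_ec = ga$new_ec))
            full[old_g, envs] <- pr$estimates
          }
          full
        }
      }
      if ("GBLUP" %in% models) {
        gb_fits <- list()
        for (j in tr_envs) {
          yj <- vals[, j]
          if (sum(!is.na(yj)) >= 3)
            gb_fits[[as.character(j)]] <- fit_gblup(yj[!is.na(yj)],
                                                    sim$inputs$K)
        }
        gb_pred_env <- sapply(gb_fits, function(f) {
          v <- stats::setNames(rep(NA_real_, n), gids)
          v[f$genotypes] <- f$g_hat
          miss <- setdiff(gids, f$genotypes)
          if (length(miss))
            v[miss] <- gblup_predict_new_geno(
              f, sim$inputs$K[miss, , drop = FALSE], sim$inputs$K)
          v
        })                                  # n x n_fitted_envs
        row_avg <- rowMeans(gb_pred_env)
        preds$GBLUP <- function(goal, envs) {
          full <- matrix(NA_real_, n, ncol(Y), dimnames = dimnames(Y))
          if (goal %in% c("CV1", "CV2")) {
            full[, as.integer(colnames(gb_pred_env))] <- gb_pred_env
          } else {
            full[, envs] <- row_avg
          }
          full
        }
      }
      for (goal in goals) {
        envs <- goal_envs(goal)
        if (is.null(envs) || !length(envs)) {
          skipped <- c(skipped, sprintf("config %d rep %d: goal %s under %s",
                                        ci, r, goal, cfg$ec_mode))
          next
        }
        if (goal == "CV2" && cfg$missing_prop == 0) {
          skipped <- c(skipped,
                       sprintf("config %d rep %d: CV2 needs missing_prop > 0",
                               ci, r))
          next
        }
        genos <- if (goal == "CV1" || grepl("^NewGeno", goal)) new_g else old_g
        for (mn in names(preds)) {
          pm <- preds[[mn]](goal, envs)
          ab <- if (goal == "CV2") {
            # only cells masked in training are scored
            msk <- sim$truth$mask
            rs <- vapply(tr_envs, function(j) {
              cells <- intersect(which(msk[, j]), old_g)
              if (length(cells) < 2) return(NA_real_)
              predictive_ability(Y[cells, j], pm[cells, j])
            }, 0)
            mean(rs, na.rm = TRUE)
          } else sim_goal_ability(pm, Y, genos, envs)
          rows[[length(rows) + 1L]] <- data.frame(
            config = ci, replicate = r, goal = goal, model = mn,
            ability = ab, n_envs = length(envs), stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}
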