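# Cross-validation scenario construction and the model x scenario harness
# that produces per-experiment predictive abilities.

met_scenarios <- c("CV1", "CV2", "NewTrial", "NewState", "NewTester",
                   "NewGenoNewYear")

seeded_folds <- function(ids, n_folds, seed) {
  # sizes differ by at most one; assignment by seeded shuffle
  set.seed(seed)
  f <- rep(seq_len(n_folds), length.out = length(ids))
  stats::setNames(sample(f), ids)
}

#' Construct a cross-validation fold plan
#'
#' Six scenarios are supported.  `CV1` partitions genotypes into `n_folds`
#' folds used identically in every experiment (whole genotypes held out).
#' `CV2` reuses the same genotype partition but permutes the fold order
#' independently within each experiment (sparse testing).  The four
#' new-environment scenarios are built on top of each CV2 training set:
#' `NewTrial` holds out folds of trials (location-years), `NewState` holds
#' out each state with at least `min_state_experiments` experiments,
#' `NewTester` holds out each tester's experiments, and `NewGenoNewYear`
#' holds out consecutive two-year blocks of experiments and additionally
#' removes from the test sets any genotype present in training.  In all
#' new-environment scenarios a test experiment is evaluated on its CV2
#' holdout genotypes only.
#'
#' @param inputs a [met_inputs] bundle (metadata must provide state, tester
#'   or year where the scenario needs them).
#' @param scenario one of `"CV1"`, `"CV2"`, `"NewTrial"`, `"NewState"`,
#'   `"NewTester"`, `"NewGenoNewYear"`.
#' @param n_folds genotype folds (default 5).
#' @param seed RNG seed; the plan is deterministic given it.
#' @param min_state_experiments minimum experiments for a state to qualify
#'   as a NewState test set (default 9).
#' @param year_block window length (years) for NewGenoNewYear (default 2).
#' @return object of class `"fold_plan"`: list with `scenario`, `seed`, and
#'   `assignments`, each a list with `train_mask` and `test_cells` (cell-
#'   level logical matrices), `test_experiments`, `new_genotypes`, `id`.
#' @export
make_folds <- function(inputs, scenario, n_folds = 5, seed = 1,
                       min_state_experiments = 9, year_block = 2) {
  scenario <- match.arg(scenario, met_scenarios)
  tr <- inputs$traits
  Obs <- tr$observed
  genos <- rownames(tr$values); exps <- colnames(tr$values)
  n <- length(genos); t_n <- length(exps)
  gf <- seeded_folds(genos, n_folds, seed)
  # per-experiment fold order permutations for CV2-derived schemes
  perm <- sapply(seq_len(t_n), function(j) sample(n_folds))  # n_folds x t
  assignments <- list()
  add <- function(train_mask, test_cells, test_experiments = character(),
                  new_genotypes = character(), id) {
    stopifnot(!any(train_mask & test_cells))
    assignments[[length(assignments) + 1L]] <<-
      list(train_mask = train_mask & Obs, test_cells = test_cells & Obs,
           test_experiments = test_experiments,
           new_genotypes = new_genotypes, id = id)
  }
  cv2_masks <- lapply(seq_len(n_folds), function(a) {
    tc <- sapply(seq_len(t_n), function(j) gf == perm[a, j])
    dimnames(tc) <- dimnames(Obs)
    tc
  })
  if (scenario == "CV1") {
    for (a in seq_len(n_folds)) {
      test_g <- genos[gf == a]
      tc <- matrix(genos %in% test_g, n, t_n, dimnames = dimnames(Obs))
      add(!tc, tc, new_genotypes = test_g, id = sprintf("CV1_f%d", a))
    }
  } else if (scenario == "CV2") {
    for (a in seq_len(n_folds)) {
      tc <- cv2_masks[[a]]
      add(!tc, tc, id = sprintf("CV2_f%d", a))
    }
  } else {
    meta <- tr$meta
    groups <- switch(scenario,
      NewTrial = {
        trial <- paste(meta$location, meta$year, sep = "_")
        tf <- seeded_folds(unique(trial), n_folds, seed + 1L)
        split(exps, tf[trial])
      },
      NewState = {
        cnt <- table(meta$state)
        ok <- names(cnt)[cnt >= min_state_experiments]
        if (!length(ok))
          stop(sprintf("scenario infeasible: no state with >= %d experiments",
                       min_state_experiments))
        split(exps, meta$state)[ok]
      },
      NewTester = split(exps, meta$tester),
      NewGenoNewYear = {
        yr <- as.integer(meta$year)
        if (anyNA(yr)) stop("scenario infeasible: year metadata missing")
        blk <- (yr - min(yr)) %/% year_block
        split(exps, blk)
      })
    for (a in seq_len(n_folds)) {
      cv2_tc <- cv2_masks[[a]]
      for (g in seq_along(groups)) {
        test_e <- groups[[g]]
        in_test <- exps %in% test_e
        tm <- !cv2_tc
        tm[, in_test] <- FALSE
        tc <- cv2_tc
        tc[, !in_test] <- FALSE
        new_g <- character()
        if (scenario == "NewGenoNewYear") {
          trained <- rowSums(tm & Obs) > 0
          tc[trained, ] <- FALSE
          new_g <- genos[!trained]
          if (!length(new_g)) next
        }
        add(tm, tc, test_experiments = test_e, new_genotypes = new_g,
            id = sprintf("%s_f%d_%s", scenario, a, names(groups)[g]))
      }
    }
    if (!length(assignments))
      stop("scenario infeasible: no valid assignments")
  }
  structure(list(scenario = scenario, seed = seed,
                 assignments = assignments),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("Fold plan: %s, %d assignment(s), seed %d\n", x$scenario,
              length(x$assignments), x$seed))
  invisible(x)
}

#' Serialise a fold plan to JSON
#'
#' Writes scenario, seed, and per-assignment test-unit lists so a run is
#' auditable and resumable.
#'
#' @param plan a [make_folds] plan.
#' @param file output path.
#' @export
write_fold_plan <- function(plan, file) {
  out <- list(scenario = plan$scenario, seed = plan$seed,
              assignments = lapply(plan$assignments, function(a) {
                idx <- which(a$test_cells, arr.ind = TRUE)
                list(id = a$id,
                     test_experiments = a$test_experiments,
                     new_genotypes = a$new_genotypes,
                     test_cells = data.frame(
                       genotype = rownames(a$test_cells)[idx[, 1]],
                       experiment = colnames(a$test_cells)[idx[, 2]]))
              }))
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE),
             file)
  invisible(plan)
}

#' Predictive ability (Pearson correlation)
#'
#' @param y observed phenotypes of the test set.
#' @param g_hat predicted genetic values, same length.
#' @return `cor(y, g_hat)`, or `NA` (the undefined-ability sentinel, excluded
#'   from meta-analysis) when fewer than 2 pairs remain or either vector has
#'   zero variance.
#' @export
predictive_ability <- function(y, g_hat) {
  keep <- is.finite(y) & is.finite(g_hat)
  y <- y[keep]; g_hat <- g_hat[keep]
  if (length(y) < 2) return(NA_real_)
  if (stats::sd(y) < 1e-12 || stats::sd(g_hat) < 1e-12) return(NA_real_)
  stats::cor(y, g_hat)
}

# ---------------------------------------------------------------------------
# The model x scenario harness
# ---------------------------------------------------------------------------

# Build training inputs from an assignment: non-training cells are masked,
# all-missing columns dropped, all-missing rows dropped (their genotypes
# become "new").
training_inputs <- function(inputs, assignment) {
  vals <- inputs$traits$values
  vals[!assignment$train_mask] <- NA
  keep_c <- colSums(!is.na(vals)) > 0
  keep_r <- rowSums(!is.na(vals)) > 0
  vals <- vals[keep_r, keep_c, drop = FALSE]
  meta <- inputs$traits$meta[keep_c, , drop = FALSE]
  ec <- ec_subset(inputs$ec, colnames(vals))
  met_inputs(trait_matrix(vals, meta), inputs$K, ec,
             X = inputs$X[keep_r, , drop = FALSE])
}

# prediction matrix over (genotype x experiment) for one model, one
# assignment; returns a function pred(genotype, experiment) via a matrix.
predict_assignment <- function(model, inputs, assignment, scenario, control) {
  full_genos <- rownames(inputs$traits$values)
  full_exps <- colnames(inputs$traits$values)
  out <- matrix(NA_real_, length(full_genos), length(full_exps),
                dimnames = list(full_genos, full_exps))
  if (is.function(model))
    return(model(inputs, assignment))
  if (grepl("^GBLUP", model)) {
    grouping <- sub("^GBLUP:?", "", model)
    tri <- training_inputs(inputs, assignment)
    vals <- tri$traits$values
    fits <- list()
    for (j in colnames(vals)) {
      yj <- vals[, j]
      if (sum(!is.na(yj)) >= 3)
        fits[[j]] <- fit_gblup(yj[!is.na(yj)], inputs$K)
    }
    if (!length(fits)) return(out)
    # per-experiment predictions for every genotype (BLUP if phenotyped,
    # kinship regression otherwise)
    per_exp <- lapply(fits, function(f) {
      v <- stats::setNames(rep(NA_real_, length(full_genos)), full_genos)
      v[f$genotypes] <- f$g_hat
      new_ids <- setdiff(full_genos, f$genotypes)
      if (length(new_ids))
        v[new_ids] <- gblup_predict_new_geno(
          f, inputs$K[new_ids, , drop = FALSE], inputs$K)
      v
    })
    if (scenario %in% c("CV1", "CV2")) {
      for (j in names(per_exp)) out[, j] <- per_exp[[j]][full_genos]
    } else {
      targets <- assignment$test_experiments
      clusters <- NULL
      if (nzchar(grouping) && grouping != "ALL") {
        meta <- inputs$traits$meta
        clusters <- stats::setNames(as.character(meta[[grouping]]),
                                    meta$experiment)
      }
      cp <- gblup_new_env_strategy(per_exp, targets, clusters)
      out[rownames(cp$estimates), targets] <- cp$estimates
    }
    return(out)
  }
  # a metfa model spec
  tri <- training_inputs(inputs, assignment)
  known <- setdiff(ec_term_names(tri$ec), "intercept")
  spec <- parse_model_spec(model, known)
  fit <- metfa(tri, spec, control)
  train_genos <- fit$genotypes
  new_genos <- setdiff(full_genos, train_genos)
  K_no <- if (length(new_genos))
    inputs$K[new_genos, , drop = FALSE]
  constant <- identical(spec$predictor_terms, "CONSTANT")
  if (scenario %in% c("CV1", "CV2")) {
    goo <- predict(fit, "Goo")
    out[train_genos, fit$experiments] <- goo$estimates
    if (length(new_genos)) {
      ano <- predict(fit, "Ano", K_new = K_no)
      out[new_genos, fit$experiments] <- ano$estimates
    }
    return(out)
  }
  targets <- assignment$test_experiments
  tmeta <- inputs$traits$meta
  tmeta <- tmeta[tmeta$experiment %in% targets, , drop = FALSE]
  new_ec <- list()
  for (nm in setdiff(ec_term_names(inputs$ec), "intercept")) {
    rr <- ec_raw_rows(inputs$ec, nm, tmeta$experiment)
    if (!is.null(rr)) new_ec[[nm]] <- rr
  }
  if (!length(new_ec)) new_ec <- NULL
  if (scenario == "NewGenoNewYear") {
    test_genos <- assignment$new_genotypes
    K_nt <- inputs$K[test_genos, , drop = FALSE]
    pr <- if (constant)
      constant_prediction(predict(fit, "Ano", K_new = K_nt), targets)
    else suppressWarnings(predict(fit, "Ann", K_new = K_nt,
                                  newdata = tmeta, new_ec = new_ec))
    out[test_genos, targets] <- pr$estimates
  } else {
    pr <- if (constant)
      constant_prediction(predict(fit, "Goo"), targets)
    else suppressWarnings(predict(fit, "Gon", newdata = tmeta,
                                  new_ec = new_ec))
    out[train_genos, targets] <- pr$estimates
  }
  out
}

#' Run a model x scenario evaluation
#'
#' For every model and fold-plan assignment the harness trains on the
#' assignment's training cells, predicts its test units with the
#' scenario-appropriate prediction operation, computes per-experiment
#' predictive ability (Pearson correlation of held-out phenotypes with
#' predictions), and averages an experiment's abilities across assignments.
#'
#' @param inputs a [met_inputs] bundle (full data; masking comes from the
#'   plan).
#' @param models character vector of model labels: EC-prior factor-model
#'   specs such as `"S+T::S+T"` (parsed by [parse_model_spec]), or GBLUP
#'   baselines `"GBLUP"`/`"GBLUP:ALL"` (constant over all training
#'   experiments), `"GBLUP:state"`, `"GBLUP:tester"` (cluster averaging).
#'   A named list mixing labels with functions
#'   `function(inputs, assignment)` returning a full genotype x experiment
#'   prediction matrix is also accepted (e.g. oracles in simulations).
#' @param plan a [make_folds] plan.
#' @param control sampler control for the factor-model fits.
#' @return an `"ability_table"` data.frame with columns `model`, `scenario`,
#'   `experiment`, `ability`, `n_test`, `fold_count`.
#' @export
run_scenario <- function(inputs, models, plan,
                         control = metfa_control()) {
  if (!is.list(models)) {
    models <- as.list(models)
    names(models) <- unlist(models)
  }
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stop("all models must be named")
  # fail fast on specs needing absent EC terms
  known <- setdiff(ec_term_names(inputs$ec), "intercept")
  for (nm in names(models))
    if (is.character(models[[nm]]) && !grepl("^GBLUP", models[[nm]]))
      parse_model_spec(models[[nm]], known)
  Y <- inputs$traits$values
  rows <- list()
  for (mi in seq_along(models)) {
    for (a in plan$assignments) {
      pred <- predict_assignment(models[[mi]], inputs, a, plan$scenario,
                                 control)
      test_exps <- colnames(Y)[colSums(a$test_cells) > 0]
      for (j in test_exps) {
        cells <- a$test_cells[, j]
        r <- predictive_ability(Y[cells, j], pred[cells, j])
        rows[[length(rows) + 1L]] <- data.frame(
          model = names(models)[mi], scenario = plan$scenario,
          experiment = j, assignment = a$id, ability = r,
          n_test = sum(cells), stringsAsFactors = FALSE)
      }
    }
  }
  raw <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(ability, n_test) ~ model + scenario +
                            experiment, data = raw, FUN = mean,
                          na.action = stats::na.omit)
  cnt <- stats::aggregate(assignment ~ model + scenario + experiment,
                          data = raw[!is.na(raw$ability), , drop = FALSE],
                          FUN = length)
  names(cnt)[4] <- "fold_count"
  out <- merge(agg, cnt, sort = TRUE)
  attr(out, "raw") <- raw
  class(out) <- c("ability_table", "data.frame")
  out
}

#' Pick the best prediction strategy from an ability table
#'
#' Returns the candidate model with the highest meta-analytic mean ability
#' across the table's experiments; ties go to the model with fewer predictor
#' terms, then to label order.
#'
#' @param table an `"ability_table"` from [run_scenario].
#' @param candidates model labels to compare (must all be present).
#' @return the selected label.
#' @export
select_best_strategy <- function(table, candidates) {
  stopifnot(all(candidates %in% table$model))
  means <- vapply(candidates, function(m) {
    tb <- table[table$model == m & !is.na(table$ability), , drop = FALSE]
    if (nrow(tb) >= 2) meta_mean_ability(tb)$mean else mean(tb$ability)
  }, 0)
  n_pred <- vapply(candidates, function(m) {
    if (grepl("^GBLUP", m) || !grepl("::", m)) return(0L)
    rhs <- sub(".*::", "", m)
    if (rhs == "O") 0L else length(strsplit(rhs, "+", fixed = TRUE)[[1]])
  }, 0L)
  ord <- order(-round(means, 10), n_pred, seq_along(candidates))
  candidates[ord[1]]
}

#' Write an ability table to CSV
#' @param table an `"ability_table"`.
#' @param file path.
#' @export
write_ability_table <- function(table, file) {
  utils::write.csv(as.data.frame(table), file, row.names = FALSE)
  invisible(table)
}
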