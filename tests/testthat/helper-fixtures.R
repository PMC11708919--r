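# Shared fixture builders: everything is generated in code at test time.

# small fully-crossed MET with categorical state/tester metadata
toy_inputs <- function(n = 12, t = 6, seed = 42, missing = 0) {
  set.seed(seed)
  K <- simulate_kinship(n, max(2, n %/% 3))
  Y <- matrix(rnorm(n * t), n, t,
              dimnames = list(rownames(K), sprintf("e%02d", 1:t)))
  if (missing > 0) Y[sample(length(Y), round(missing * length(Y)))] <- NA
  meta <- data.frame(experiment = colnames(Y), location = colnames(Y),
                     year = 2014 + (seq_len(t) - 1) %% 4,
                     state = paste0("S", 1 + (seq_len(t) - 1) %% 2),
                     tester = paste0("T", 1 + (seq_len(t) - 1) %% 3),
                     stringsAsFactors = FALSE)
  traits <- trait_matrix(Y, meta)
  ec <- ec_design_set(meta, list(S = "state", T = "tester"))
  met_inputs(traits, K, ec)
}

# a sampler context + freshly initialised state for block-level tests
toy_ctx <- function(inputs, k_max = 2, seed = 1, ...) {
  ctl <- metfa_control(k_max = k_max, n_iter = 10, burn_in = 5, seed = seed,
                       ...)
  spec <- parse_model_spec("S+T::S+T",
                           setdiff(metfa:::ec_term_names(inputs$ec),
                                   "intercept"))
  metfa:::metfa_setup(inputs, spec, ctl)
}

# 1-genotype, 1-experiment context for conjugate-algebra oracles
unit_ctx <- function(y = 2, k_max = 1, ...) {
  K <- matrix(1, 1, 1, dimnames = list("g1", "g1"))
  traits <- trait_matrix(matrix(y, 1, 1, dimnames = list("g1", "e1")))
  inputs <- met_inputs(traits, K)
  ctl <- metfa_control(k_max = k_max, n_iter = 10, burn_in = 5, ...)
  spec <- parse_model_spec("O::O", character())
  metfa:::metfa_setup(inputs, spec, ctl)
}

# batch-means Monte-Carlo standard error (robust to autocorrelation)
batch_se <- function(x, n_batch = 30) {
  bs <- floor(length(x) / n_batch)
  means <- vapply(seq_len(n_batch),
                  function(b) mean(x[((b - 1) * bs + 1):(b * bs)]), 0)
  sd(means) / sqrt(n_batch)
}

# the parameter-recovery fixture: clear 2-factor structure, no missing data
recovery_fixture <- function(seed = 11) {
  simulate_met(sim_config(n_lines = 100, t_train = 10, t_test = 4,
                          k_true = 2, z_cols = 25, main_effect_prop = 0.4,
                          unpredictable_prop = 0, h2 = 0.8,
                          factor_share = 0.8, seed = seed))
}
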