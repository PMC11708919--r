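#' metfa: factor-analytic mixed models for multi-environment trials
#'
#' Fits a Bayesian sparse factor-analytic multivariate linear mixed model to a
#' genotype x experiment trait matrix, with the per-experiment factor loadings
#' modelled as regressions on environmental covariates (ECs).  The fitted
#' object supports prediction of genetic values for old/new genotypes in
#' old/new environments, GBLUP baselines, standard MET cross-validation
#' scenarios, and meta-analytic comparison of predictive abilities.
#'
#' @docType package
#' @name metfa-package
#' @aliases metfa-pkg
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# TraitMatrix
# ---------------------------------------------------------------------------

#' Construct a genotype x experiment trait matrix
#'
#' The central phenotype container: a numeric matrix with genotypes in rows
#' and experiments (location-year-tester combinations) in columns, a logical
#' mask of observed cells, and per-experiment metadata.  Missing phenotypes
#' are `NA` in `values` and `FALSE` in the mask; internally the mask is
#' authoritative and no sentinel value is ever used in arithmetic.
#'
#' @param values numeric matrix, genotypes x experiments, with unique
#'   rownames (genotype ids) and colnames (experiment ids); `NA` = missing.
#' @param meta data.frame of per-experiment metadata with columns
#'   `experiment`, `location`, `year`, `state`, `tester`.  One row per column
#'   of `values`.  If `NULL`, a minimal frame is synthesised from the column
#'   names.
#' @return an object of class `"trait_matrix"`: a list with elements
#'   `values`, `observed` (logical mask), and `meta`.
#' @export
trait_matrix <- function(values, meta = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("e", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicated genotype ids in trait matrix rows")
  if (anyDuplicated(colnames(values)))
    stop("duplicated experiment ids in trait matrix columns")
  if (is.null(meta)) {
    meta <- data.frame(experiment = colnames(values),
                       location = colnames(values),
                       year = NA_integer_,
                       state = NA_character_,
                       tester = NA_character_,
                       stringsAsFactors = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("experiment", "location", "year", "state", "tester")
  for (cn in setdiff(need, names(meta))) meta[[cn]] <- NA
  if (!setequal(meta$experiment, colnames(values)))
    stop("metadata experiment ids do not match trait matrix columns")
  meta <- meta[match(colnames(values), meta$experiment), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values,
                 observed = !is.na(values),
                 meta = meta),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("Trait matrix: %d genotypes x %d experiments (%.1f%% observed)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$observed)))
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

#' Experiment identifier from metadata
#'
#' The display id of an experiment is `<location>_<year>_<tester>`; the
#' metadata columns remain authoritative.
#'
#' @param meta data.frame with `location`, `year`, `tester` columns.
#' @return character vector of ids.
#' @export
experiment_id <- function(meta) {
  paste(meta$location, meta$year, meta$tester, sep = "_")
}

# ---------------------------------------------------------------------------
# Kinship
# ---------------------------------------------------------------------------

#' Validate a genomic relationship matrix
#'
#' Checks symmetry (tolerance 1e-8) and positive semi-definiteness up to
#' numerical noise (smallest eigenvalue >= -1e-8), and that ids are unique.
#'
#' @param K square numeric matrix with matching row/col names (genotype ids).
#' @return `K`, invisibly symmetrised, with validated dimnames.
#' @export
kinship <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("kinship matrix must be square")
  if (is.null(rownames(K))) rownames(K) <- paste0("g", seq_len(nrow(K)))
  if (is.null(colnames(K))) colnames(K) <- rownames(K)
  if (anyDuplicated(rownames(K))) stop("duplicated kinship ids")
  if (max(abs(K - t(K))) > 1e-8)
    stop("kinship matrix is not symmetric (tolerance 1e-8)")
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("kinship matrix is not PSD: smallest eigenvalue %.3e",
                 min(ev)))
  K
}

# ---------------------------------------------------------------------------
# EC design sets
# ---------------------------------------------------------------------------

#' Build a set of environmental-covariate design matrices
#'
#' Each EC term becomes a t x p_l design matrix over the t experiments.  The
#' first term is always a single intercept column.  Categorical terms are
#' coded as full one-hot indicators (over-parameterised; the shared per-term
#' prior variance absorbs the redundancy, random-effect style).  Quantitative
#' terms are centred and scaled to unit variance column-wise, and the
#' transform parameters are stored so the same scaling can be applied to new
#' environments at prediction time.
#'
#' @param meta per-experiment metadata data.frame (one row per experiment, in
#'   trait-matrix column order) used to resolve terms given as column names.
#' @param terms named list; each element is either the name of a column of
#'   `meta` (character/factor columns give categorical terms, numeric columns
#'   quantitative ones) or a numeric matrix/data.frame with one row per
#'   experiment (a multi-column quantitative term, e.g. weather eigenvectors).
#' @param experiments character vector of experiment ids (defaults to
#'   `meta$experiment`).
#' @return an object of class `"ec_design_set"`: list with `experiments` and
#'   `terms`, the latter an ordered list of term records
#'   `(name, design, kind, levels|center/scale)` whose first entry is the
#'   intercept.
#' @export
ec_design_set <- function(meta, terms = list(), experiments = meta$experiment) {
  experiments <- as.character(experiments)
  t_n <- length(experiments)
  out <- list(list(name = "intercept",
                   design = matrix(1, t_n, 1,
                                   dimnames = list(experiments, "intercept")),
                   kind = "categorical"))
  nms <- names(terms)
  if (length(terms) && (is.null(nms) || any(nms == "")))
    stop("all EC terms must be named")
  if (anyDuplicated(c("intercept", nms))) stop("duplicate EC term names")
  for (nm in nms) {
    spec <- terms[[nm]]
    src <- NULL
    if (is.character(spec) && length(spec) == 1L) {
      if (!spec %in% names(meta))
        stop(sprintf("EC term '%s': column '%s' not in metadata", nm, spec))
      src <- spec
      v <- meta[[spec]]
      if (is.numeric(v)) {
        spec <- matrix(v, ncol = 1, dimnames = list(experiments, spec))
      } else {
        lev <- sort(unique(as.character(v)))
        D <- outer(as.character(v), lev, "==") * 1
        dimnames(D) <- list(experiments, lev)
        out[[length(out) + 1L]] <- list(name = nm, design = D,
                                        kind = "categorical", levels = lev,
                                        source = spec)
        next
      }
    }
    D <- as.matrix(spec)
    storage.mode(D) <- "double"
    if (nrow(D) != t_n)
      stop(sprintf("EC term '%s' has %d rows; expected %d", nm, nrow(D), t_n))
    ctr <- colMeans(D)
    scl <- apply(D, 2, stats::sd)
    scl[scl < 1e-12] <- 1
    D <- sweep(sweep(D, 2, ctr, "-"), 2, scl, "/")
    rownames(D) <- experiments
    if (is.null(colnames(D))) colnames(D) <- paste0(nm, seq_len(ncol(D)))
    out[[length(out) + 1L]] <- list(name = nm, design = D,
                                    kind = "quantitative",
                                    center = ctr, scale = scl, source = src)
  }
  structure(list(experiments = experiments, terms = out,
                 recipe = list(meta = meta, terms = terms)),
            class = "ec_design_set")
}

# Rebuild an EC design set on a subset of experiments from the stored recipe
# (categorical levels and quantitative scalings are re-derived from the
# subset, which is what training-time construction means under resampling).
ec_subset <- function(ec, experiment_ids) {
  meta <- ec$recipe$meta
  keep <- match(experiment_ids, ec$experiments)
  if (anyNA(keep)) stop("unknown experiment ids in ec_subset")
  meta_sub <- meta[keep, , drop = FALSE]
  terms_sub <- lapply(ec$recipe$terms, function(tm)
    if (is.character(tm) && length(tm) == 1L) tm
    else as.matrix(tm)[keep, , drop = FALSE])
  names(terms_sub) <- names(ec$recipe$terms)
  ec_design_set(meta_sub, terms_sub, experiments = experiment_ids)
}

# Raw (untransformed) covariate rows of a matrix-valued term for a set of
# experiments, for use as new_ec at prediction time.
ec_raw_rows <- function(ec, term, experiment_ids) {
  tm <- ec$recipe$terms[[term]]
  if (is.null(tm) || (is.character(tm) && length(tm) == 1L)) return(NULL)
  as.matrix(tm)[match(experiment_ids, ec$experiments), , drop = FALSE]
}

#' @export
print.ec_design_set <- function(x, ...) {
  cat(sprintf("EC design set over %d experiments:\n", length(x$experiments)))
  for (tm in x$terms)
    cat(sprintf("  %-12s %-12s %d column(s)\n", tm$name, tm$kind,
                ncol(tm$design)))
  invisible(x)
}

ec_term_names <- function(ec) vapply(ec$terms, `[[`, "", "name")

ec_term <- function(ec, name) {
  i <- match(name, ec_term_names(ec))
  if (is.na(i)) stop(sprintf("unknown EC term '%s'", name))
  ec$terms[[i]]
}

#' EC design rows for new environments
#'
#' Applies a trained term's coding to new environments: categorical terms are
#' one-hot coded over the training levels (a level absent from training
#' contributes an all-zero row, with a warning naming the level);
#' quantitative terms are transformed with the stored training centring and
#' scaling.
#'
#' @param ec an [ec_design_set].
#' @param term term name.
#' @param newmeta metadata data.frame for the new environments (for terms
#'   built from metadata columns) or a numeric matrix with the term's raw
#'   columns (for matrix terms).
#' @param source for metadata-derived categorical terms, the metadata column
#'   to read (defaults to the term name).
#' @return numeric matrix, new environments x term columns.
#' @export
ec_new_design <- function(ec, term, newmeta, source = NULL) {
  tm <- ec_term(ec, term)
  if (is.null(source))
    source <- if (!is.null(tm$source)) tm$source else term
  if (term == "intercept")
    return(matrix(1, NROW(newmeta), 1))
  if (tm$kind == "categorical") {
    v <- as.character(if (is.data.frame(newmeta)) newmeta[[source]] else newmeta)
    unseen <- setdiff(unique(v), tm$levels)
    if (length(unseen))
      warning(sprintf("EC term '%s': level(s) %s unseen in training contribute zero",
                      term, paste(unseen, collapse = ", ")))
    D <- outer(v, tm$levels, "==") * 1
    colnames(D) <- tm$levels
    D
  } else {
    D <- as.matrix(if (is.data.frame(newmeta) && source %in% names(newmeta))
      newmeta[[source]] else newmeta)
    storage.mode(D) <- "double"
    if (ncol(D) != length(tm$center))
      stop(sprintf("EC term '%s': expected %d column(s), got %d",
                   term, length(tm$center), ncol(D)))
    sweep(sweep(D, 2, tm$center, "-"), 2, tm$scale, "/")
  }
}

# ---------------------------------------------------------------------------
# Model-spec grammar
# ---------------------------------------------------------------------------

#' Parse a model-specification label
#'
#' Model labels name which EC terms enter the loading prior (before the
#' `"::"`) and which are used to predict loadings in new environments (after
#' it), e.g. `"S+T::S+T"` or `"S+T::T"`.  `"O"` before the `"::"` means an
#' intercept-only prior (no ECs); `"O"` after it means no EC-based loading
#' prediction -- new-environment predictions fall back to the constant
#' (experiment-average) strategy.
#'
#' @param spec string of the form `"<terms>::<terms>"`, each side a
#'   `"+"`-joined list of term names or `"O"`.
#' @param known_terms character vector of available (non-intercept) EC term
#'   names; used for validation and to normalise term order.
#' @return object of class `"model_spec"`: list with `prior_terms` (always
#'   including `"intercept"`), `predictor_terms` (character vector, or the
#'   sentinel `"CONSTANT"`), and the canonical `label`.
#' @export
parse_model_spec <- function(spec, known_terms = character()) {
  spec <- gsub("[[:space:]]", "", spec)
  parts <- strsplit(spec, "::", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !nzchar(parts[1]) || !nzchar(parts[2]))
    stop(sprintf("malformed model spec '%s': expected '<terms>::<terms>'", spec))
  side <- function(s, role) {
    if (s == "O") return(character())
    tms <- strsplit(s, "+", fixed = TRUE)[[1]]
    if (any(!nzchar(tms)))
      stop(sprintf("malformed model spec '%s'", spec))
    bad <- setdiff(tms, known_terms)
    if (length(bad))
      stop(sprintf("unknown EC term(s) in %s side: %s",
                   role, paste(bad, collapse = ", ")))
    known_terms[sort(match(unique(tms), known_terms))]
  }
  prior <- side(parts[1], "prior")
  pred <- side(parts[2], "predictor")
  if (parts[2] == "O") pred <- "CONSTANT"
  if (!identical(pred, "CONSTANT") && length(setdiff(pred, prior)))
    stop(sprintf("predictor term(s) %s not in the prior side",
                 paste(setdiff(pred, prior), collapse = ", ")))
  lab <- paste0(if (length(prior)) paste(prior, collapse = "+") else "O",
                "::",
                if (identical(pred, "CONSTANT")) "O"
                else paste(pred, collapse = "+"))
  structure(list(prior_terms = c("intercept", prior),
                 predictor_terms = pred,
                 label = lab),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec:", x$label, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Model inputs and validation
# ---------------------------------------------------------------------------

#' Bundle the inputs of a MET factor model
#'
#' @param traits a [trait_matrix].
#' @param K genomic relationship matrix covering (at least) all genotypes in
#'   `traits`; validated with [kinship()].
#' @param ec an [ec_design_set] over the experiments of `traits` (default:
#'   intercept only).
#' @param X fixed-effect design matrix, one row per genotype row of `traits`
#'   (default a single intercept column).
#' @return object of class `"met_inputs"`.
#' @export
met_inputs <- function(traits, K, ec = NULL, X = NULL) {
  stopifnot(inherits(traits, "trait_matrix"))
  K <- kinship(K)
  n <- nrow(traits$values)
  if (is.null(ec))
    ec <- ec_design_set(traits$meta)
  if (is.null(X))
    X <- matrix(1, n, 1, dimnames = list(rownames(traits$values), "(Intercept)"))
  X <- as.matrix(X)
  structure(list(traits = traits, K = K, ec = ec, X = X),
            class = "met_inputs")
}

#' @export
print.met_inputs <- function(x, ...) {
  print(x$traits)
  cat(sprintf("Kinship: %d genotypes; EC terms: %s\n", nrow(x$K),
              paste(ec_term_names(x$ec), collapse = ", ")))
  invisible(x)
}

#' Validate model inputs
#'
#' Report-only checker for the joint invariants of a [met_inputs] bundle:
#' kinship id coverage, symmetry/PSD-ness, all-missing trait columns,
#' fixed-design rank, EC design alignment.  Never mutates its argument.
#'
#' @param inputs a [met_inputs] object.
#' @return data.frame with columns `component`, `severity`, `message`; zero
#'   rows if everything passes.  Attribute `"ok"` is `TRUE` iff no row has
#'   severity `"error"`.
#' @export
validate_inputs <- function(inputs) {
  rep_ <- data.frame(component = character(), severity = character(),
                     message = character(), stringsAsFactors = FALSE)
  add <- function(component, severity, message)
    rbind(rep_, data.frame(component = component, severity = severity,
                           message = message, stringsAsFactors = FALSE))
  tr <- inputs$traits
  missing_ids <- setdiff(rownames(tr$values), rownames(inputs$K))
  if (length(missing_ids))
    rep_ <- add("kinship", "error",
                sprintf("genotype id(s) absent from kinship: %s",
                        paste(missing_ids, collapse = ", ")))
  allmiss <- colnames(tr$values)[colSums(tr$observed) == 0]
  for (j in allmiss)
    rep_ <- add("traits", "warning",
                sprintf("experiment '%s' has no observed phenotypes", j))
  if (qr(inputs$X)$rank < ncol(inputs$X))
    rep_ <- add("fixed_design", "error", "fixed design is rank deficient")
  if (!identical(inputs$ec$experiments, colnames(tr$values)))
    rep_ <- add("ec", "error",
                "EC design experiments do not match trait matrix columns")
  ev_min <- min(eigen(inputs$K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8)
    rep_ <- add("kinship", "error",
                sprintf("kinship not PSD (min eigenvalue %.3e)", ev_min))
  attr(rep_, "ok") <- !any(rep_$severity == "error")
  rep_
}

# ---------------------------------------------------------------------------
# CSV interfaces
# ---------------------------------------------------------------------------

#' Read a trait matrix and its metadata from CSV
#'
#' The trait CSV has the genotype id in its first column and one column per
#' experiment, with the literal string `"NA"` for missing cells.  The
#' metadata CSV is keyed by experiment id and carries `location`, `year`,
#' `state`, `tester`.
#'
#' @param values_file path to the trait CSV.
#' @param meta_file optional path to the metadata CSV.
#' @return a [trait_matrix].
#' @export
read_trait_matrix <- function(values_file, meta_file = NULL) {
  d <- utils::read.csv(values_file, check.names = FALSE,
                       stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(d[[1]])
  meta <- if (!is.null(meta_file))
    utils::read.csv(meta_file, stringsAsFactors = FALSE) else NULL
  trait_matrix(m, meta)
}

#' Write a trait matrix (and optionally metadata) to CSV
#' @param x a [trait_matrix].
#' @param values_file,meta_file output paths (`meta_file = NULL` skips it).
#' @return invisibly, `x`.
#' @export
write_trait_matrix <- function(x, values_file, meta_file = NULL) {
  d <- data.frame(genotype = rownames(x$values), x$values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(d, values_file, row.names = FALSE)
  if (!is.null(meta_file))
    utils::write.csv(x$meta, meta_file, row.names = FALSE)
  invisible(x)
}

#' Read a square kinship CSV (header and first column both ids)
#' @param file path.
#' @return validated kinship matrix.
#' @export
read_kinship <- function(file) {
  d <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(d[[1]])
  kinship(m)
}

#' Write a kinship matrix to CSV
#' @param K kinship matrix.
#' @param file path.
#' @export
write_kinship <- function(K, file) {
  d <- data.frame(id = rownames(K), K, check.names = FALSE)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(K)
}
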