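# MET data engineering: experiment splitting, Chauvenet-type outlier
# filtering, BLUEs under four field-design cases, hybrid -> parent genotype
# inference, the VanRaden genomic relationship matrix, and growth-stage
# weather environmental covariates.

#' Split plot-level data into tester-family experiments
#'
#' One experiment per (trial, tester) combination with at least
#' `min_hybrids` distinct hybrid genotypes; smaller families are dropped
#' (logged in the `"dropped"` attribute).
#'
#' @param plots data.frame with at least `trial`, `tester`, `hybrid`, and a
#'   trait `value` column (plus optional `replicate`, `block`, `P1`).
#' @param min_hybrids minimum distinct hybrids (default 50).
#' @return named list of per-experiment data.frames, keyed
#'   `<trial>_<tester>`, with attribute `"dropped"`.
#' @export
split_experiments <- function(plots, min_hybrids = 50) {
  stopifnot(all(c("trial", "tester", "hybrid") %in% names(plots)))
  key <- paste(plots$trial, plots$tester, sep = "_")
  parts <- split(plots, key)
  n_hyb <- vapply(parts, function(d) length(unique(d$hybrid)), 0L)
  dropped <- names(parts)[n_hyb < min_hybrids]
  out <- parts[n_hyb >= min_hybrids]
  attr(out, "dropped") <- dropped
  out
}

#' Flag outliers by a Chauvenet-type criterion
#'
#' A value is flagged when its expected count of equally extreme values
#' under a normal fitted to the sample is below one:
#' `m * 2 * (1 - pnorm(|v - mean| / sd)) < 1` with `m` the sample size.
#' The same rule applies to trial means for across-trial filtering.  Note
#' the criterion depends on `m`: enlarging the sample can flag a previously
#' unflagged value.
#'
#' @param values numeric vector (>= 3 values).
#' @return logical mask of flagged values (`sd = 0` flags nothing).
#' @export
flag_outliers <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 3) stop("flag_outliers needs at least 3 values")
  m <- length(v)
  mu <- mean(v); s <- stats::sd(v)
  out <- rep(FALSE, length(values))
  if (s < 1e-12) return(out)
  z <- abs(values - mu) / s
  exp_count <- m * 2 * stats::pnorm(z, lower.tail = FALSE)
  out[!is.na(values)] <- exp_count[!is.na(values)] < 1
  out & !is.na(values)
}

#' Best linear unbiased estimates of hybrid means in one experiment
#'
#' The model is chosen from the design structure: >=2 replicates and >=2
#' blocks per replicate fit `value ~ hybrid + replicate + (1|replicate:block)`
#' (lme4, REML); >=2 replicates with one block fit
#' `value ~ replicate + hybrid`; one replicate with >=2 blocks fit
#' `value ~ hybrid + (1|block)`; otherwise `value ~ hybrid`.  Returned
#' BLUEs are marginal hybrid means: intercept + hybrid effect + the
#' equal-weight average over replicate levels (random block effects do not
#' shift the marginal mean).
#'
#' @param experiment data.frame with `hybrid`, `value`, and optional
#'   `replicate`, `block` columns.
#' @return named numeric vector of per-hybrid BLUEs (hybrids whose values
#'   were all removed are absent).
#' @export
fit_blues <- function(experiment) {
  d <- experiment[!is.na(experiment$value), , drop = FALSE]
  if (!nrow(d)) stop("no data after outlier removal")
  d$hybrid <- factor(d$hybrid)
  n_rep <- if ("replicate" %in% names(d))
    length(unique(d$replicate)) else 1L
  n_blk <- if ("block" %in% names(d))
    max(tapply(d$block, if (n_rep > 1) d$replicate else rep(1, nrow(d)),
               function(b) length(unique(b)))) else 1L
  hybrids <- levels(d$hybrid)
  if (n_rep >= 2) d$replicate <- factor(d$replicate)
  if (n_blk >= 2) d$block <- factor(d$block)
  if (n_rep >= 2 && n_blk >= 2) {
    fit <- lme4::lmer(value ~ hybrid + replicate + (1 | replicate:block),
                      data = d, REML = TRUE)
    fe <- lme4::fixef(fit)
  } else if (n_rep >= 2) {
    fe <- stats::coef(stats::lm(value ~ hybrid + replicate, data = d))
  } else if (n_blk >= 2) {
    fit <- lme4::lmer(value ~ hybrid + (1 | block), data = d, REML = TRUE)
    fe <- lme4::fixef(fit)
  } else {
    fe <- stats::coef(stats::lm(value ~ hybrid, data = d))
  }
  hyb_eff <- stats::setNames(rep(0, length(hybrids)), hybrids)
  hh <- grep("^hybrid", names(fe), value = TRUE)
  hyb_eff[sub("^hybrid", "", hh)] <- fe[hh]
  rep_eff <- fe[grep("^replicate", names(fe))]
  rep_mean <- if (length(rep_eff))
    sum(c(0, rep_eff), na.rm = TRUE) / (length(rep_eff) + 1) else 0
  blue <- fe[["(Intercept)"]] + hyb_eff + rep_mean
  # hybrids that lost every record give NA coefficients -> drop
  blue[!is.na(blue)]
}

#' Assemble per-experiment BLUEs into a trait matrix
#'
#' Rows are inbred Parent 1 ids, columns are experiments
#' (location-year-tester); a P1 crossed to two testers occupies one row and
#' two columns.  Cells without a BLUE are missing.
#'
#' @param blues named list (by experiment id) of named BLUE vectors keyed by
#'   hybrid.
#' @param p1_of named character vector mapping hybrid -> P1.
#' @param meta optional experiment metadata passed to [trait_matrix].
#' @return a [trait_matrix].
#' @export
assemble_trait_matrix <- function(blues, p1_of, meta = NULL) {
  p1s <- sort(unique(p1_of[unlist(lapply(blues, names))]))
  if (anyNA(p1s)) stop("every hybrid must map to a P1")
  M <- matrix(NA_real_, length(p1s), length(blues),
              dimnames = list(p1s, names(blues)))
  for (e in names(blues)) {
    b <- blues[[e]]
    rows <- p1_of[names(b)]
    dup <- duplicated(rows)
    if (any(dup))
      stop(sprintf("duplicate (P1, experiment) BLUEs in '%s': %s", e,
                   paste(unique(rows[dup]), collapse = ", ")))
    M[rows, e] <- b
  }
  trait_matrix(M, meta)
}

#' Infer parent genotypes from hybrid dosages
#'
#' For each site in each hybrid: a homozygous dosage (0 or 2) is assigned to
#' both parents; a heterozygous dosage assigns the tester 0 if any other
#' hybrid of the same tester is 0 at the site (so the tester cannot carry
#' the alternate allele), otherwise 2, with the P1 taking the complementary
#' homozygote.  Sites where same-tester hybrids are both 0 and 2 while the
#' focal hybrid is 1 are irreconcilable: both parents are set missing and
#' the conflict is logged.  Hybrids whose tester occurs in no other hybrid
#' are dropped.
#'
#' @param hybrids dosage matrix (hybrids x sites, values 0/1/2/NA).
#' @param tester_of named character vector mapping hybrid id -> tester id.
#' @return list with `P1` (hybrids x sites dosage matrix of Parent-1
#'   genotypes), `tester` (testers x sites), `conflicts` (count), `dropped`
#'   (hybrid ids).
#' @export
infer_parent_genotypes <- function(hybrids, tester_of) {
  tester_of <- tester_of[rownames(hybrids)]
  tab <- table(tester_of)
  dropped <- names(tester_of)[tester_of %in% names(tab)[tab < 2]]
  keep <- setdiff(rownames(hybrids), dropped)
  H <- hybrids[keep, , drop = FALSE]
  tof <- tester_of[keep]
  P1 <- H
  TS <- matrix(NA_real_, length(unique(tof)), ncol(H),
               dimnames = list(sort(unique(tof)), colnames(H)))
  conflicts <- 0L
  for (ts in rownames(TS)) {
    sub <- H[tof == ts, , drop = FALSE]
    any0 <- apply(sub == 0, 2, any, na.rm = TRUE)
    any2 <- apply(sub == 2, 2, any, na.rm = TRUE)
    anyh <- apply(sub == 1, 2, any, na.rm = TRUE)
    conflict <- any0 & any2       # tester implied both 0 and 2
    # tester dosage: 0 if any hybrid is 0, else 2 given any evidence
    TS[ts, ] <- ifelse(conflict, NA,
                       ifelse(any0, 0, ifelse(any2 | anyh, 2, NA)))
    for (i in which(tof == ts)) {
      het <- which(H[i, ] == 1)
      if (!length(het)) next
      conf <- het[conflict[het]]
      ok <- setdiff(het, conf)
      P1[i, ok] <- 2 - TS[ts, ok]
      P1[i, conf] <- NA
      conflicts <- conflicts + length(conf)
    }
  }
  list(P1 = P1, tester = TS, conflicts = conflicts, dropped = dropped)
}

#' VanRaden genomic relationship matrix
#'
#' `G = (M - 2P)(M - 2P)' / (2 sum p_s (1 - p_s))` with allele frequencies
#' `p_s` computed from the supplied dosage matrix; missing dosages are
#' mean-imputed per site before centring, and monomorphic sites are
#' dropped.
#'
#' @param markers dosage matrix (individuals x sites, 0/1/2/NA).
#' @param p optional externally supplied allele frequencies.
#' @return individuals x individuals kinship matrix.
#' @export
vanraden_grm <- function(markers, p = NULL) {
  M <- as.matrix(markers)
  if (is.null(p)) p <- colMeans(M, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1 & !is.na(p)
  M <- M[, keep, drop = FALSE]; p <- p[keep]
  if (!ncol(M)) stop("no polymorphic sites")
  for (j in seq_len(ncol(M))) M[is.na(M[, j]), j] <- 2 * p[j]
  Wc <- sweep(M, 2, 2 * p, "-")
  G <- tcrossprod(Wc) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(markers), rownames(markers))
  G
}

#' Daily corn growing degree days and their accumulation
#'
#' Temperatures are floored at 50 F and the maximum capped at 86 F; the
#' default `divisor = 2` gives the standard corn GDD
#' `(Tmax' + Tmin')/2 - 50`.  `divisor = 1` reproduces the uncapped-mean
#' variant `(Tmax' + Tmin') - 50`, which roughly doubles accumulation and is
#' provided for comparison only.  Days with `Tmax < Tmin` are skipped with a
#' warning.
#'
#' @param weather data.frame with `date`, `tmax`, `tmin` (degrees F) and
#'   optionally `precip` plus further daily variables.
#' @param divisor 2 (standard, default) or 1.
#' @return `weather` with added columns `gdd` and `agdd` (running sum from
#'   the first day); skipped days are removed.
#' @export
compute_gdd_series <- function(weather, divisor = 2) {
  stopifnot(all(c("date", "tmax", "tmin") %in% names(weather)))
  w <- weather[order(weather$date), , drop = FALSE]
  bad <- w$tmax < w$tmin
  if (any(bad)) {
    warning(sprintf("%d day(s) with tmax < tmin skipped", sum(bad)))
    w <- w[!bad, , drop = FALSE]
  }
  tmax <- pmin(pmax(w$tmax, 50), 86)
  tmin <- pmax(w$tmin, 50)
  w$gdd <- pmax((tmax + tmin) / divisor - 50, 0)
  w$agdd <- cumsum(w$gdd)
  w
}

#' Default 23-stage maize growth-stage table
#'
#' Stage names VE, V1-V18, VT, R1, R2, and the merged R3-R6, with
#' illustrative accumulated-GDD entry thresholds (the package does not ship
#' calibrated thresholds; supply your own table for real analyses).
#'
#' @return data.frame with `stage` and `agdd_threshold` (strictly
#'   increasing; units are F-based GDD accumulated from planting).
#' @export
default_stage_table <- function() {
  stages <- c("VE", paste0("V", 1:18), "VT", "R1", "R2", "R3-R6")
  thr <- c(0, seq(115, 115 + 84 * 17, by = 84), 1650, 1750, 1925, 2450)
  data.frame(stage = stages, agdd_threshold = thr,
             stringsAsFactors = FALSE)
}

#' Partition a season into growth stages by accumulated GDD
#'
#' Day `d` belongs to stage `s` iff `AGDD(d)` lies in
#' `[threshold_s, threshold_{s+1})`; stages never entered (season too
#' short) are empty.
#'
#' @param agdd nondecreasing numeric vector of accumulated GDD per day.
#' @param stages stage table as from [default_stage_table()].
#' @return factor of per-day stage labels (levels = all stages, so empty
#'   stages are visible in `table()`).
#' @export
stage_partition <- function(agdd, stages = default_stage_table()) {
  stopifnot(nrow(stages) >= 1, !is.unsorted(stages$agdd_threshold,
                                            strictly = TRUE))
  idx <- findInterval(agdd, stages$agdd_threshold)
  idx[idx < 1] <- 1L
  factor(stages$stage[idx], levels = stages$stage)
}

#' Growth-stage weather environmental covariates for one trial
#'
#' Averages each weather variable and GDD within each growth stage, and
#' appends the season totals AGDD and accumulated precipitation (APRE).
#' With 11 weather variables and 23 stages this yields
#' (11 + 1) x 23 + 2 = 278 features.  Stages the season never reached give
#' missing features (to be mean-imputed downstream).
#'
#' @param weather daily table as returned by [compute_gdd_series] (must
#'   contain `gdd`, `agdd`, `precip`, and the weather variables).
#' @param variables character vector of the weather variable columns.
#' @param stages stage table.
#' @return named numeric vector of ECs
#'   (`<variable>_<stage>` ..., `AGDD`, `APRE`).
#' @export
build_weather_ecs <- function(weather,
                              variables = setdiff(names(weather),
                                                  c("date", "gdd", "agdd",
                                                    "precip")),
                              stages = default_stage_table()) {
  stopifnot(all(c("gdd", "agdd") %in% names(weather)))
  st <- stage_partition(weather$agdd, stages)
  vars <- c(variables, "gdd")
  out <- numeric(0)
  for (v in vars) {
    m <- tapply(weather[[v]], st, mean)
    names(m) <- paste(v, levels(st), sep = "_")
    out <- c(out, m)
  }
  apre <- if ("precip" %in% names(weather)) sum(weather$precip) else NA_real_
  c(out, AGDD = max(weather$agdd), APRE = apre)
}

#' Scaled eigenvector features from an EC table or similarity matrix
#'
#' For a trials x variables table: columns are standardised, the trial-level
#' covariance is eigendecomposed, and the eigenvectors scaled by the square
#' roots of their eigenvalues are returned (top `n_components`).  For a PSD
#' similarity matrix (e.g. a kinship), its eigenvectors are scaled likewise.
#' The default component count is the smallest explaining 95% of variance,
#' capped at one less than the number of rows.
#'
#' @param x trials x variables matrix (missing cells mean-imputed
#'   column-wise), or a square PSD similarity matrix.
#' @param n_components number of components (default: 95% of variance).
#' @return rows x n_components matrix of scaled eigenvector features.
#' @export
ec_eigenfeatures <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  is_sim <- nrow(x) == ncol(x) && max(abs(x - t(x))) < 1e-8
  if (is_sim) {
    S <- x
  } else {
    for (j in seq_len(ncol(x))) {
      cj <- x[, j]
      if (anyNA(cj)) x[is.na(cj), j] <- mean(cj, na.rm = TRUE)
    }
    sds <- apply(x, 2, stats::sd)
    sds[sds < 1e-12] <- 1
    xs <- sweep(sweep(x, 2, colMeans(x), "-"), 2, sds, "/")
    S <- tcrossprod(xs) / max(ncol(xs) - 1, 1)
  }
  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (is.null(n_components)) {
    cum <- cumsum(ev) / sum(ev)
    n_components <- min(which(cum >= 0.95), nrow(x) - 1L)
  }
  n_components <- min(n_components, length(ev))
  F_ <- eg$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_components)]), n_components)
  dimnames(F_) <- list(rownames(x), paste0("EV", seq_len(n_components)))
  F_
}
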