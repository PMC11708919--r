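# Preprocessing: experiment splitting, outlier filtering, BLUEs, parent
# genotype inference, VanRaden GRM, and weather EC construction.

test_that("experiment splitting counts distinct hybrids, not plots", {
  plots <- data.frame(
    trial = "L1_2015",
    tester = rep(c("A", "B"), c(120, 80)),
    hybrid = c(paste0("h", rep(1:60, 2)), paste0("j", rep(1:40, 2))),
    value = rnorm(200))
  out <- split_experiments(plots, min_hybrids = 50)
  expect_equal(names(out), "L1_2015_A")
  expect_equal(attr(out, "dropped"), "L1_2015_B")
  # 60 hybrids x 2 reps passes at exactly threshold 60
  out60 <- split_experiments(plots, min_hybrids = 60)
  expect_equal(names(out60), "L1_2015_A")
  # no-filter limit keeps every (trial, tester)
  out1 <- split_experiments(plots, min_hybrids = 1)
  expect_equal(length(out1), 2)
})

test_that("the Chauvenet-type criterion flags the classic example and no mild values", {
  v <- c(1, 2, 3, 4, 100)
  fl <- flag_outliers(v)
  expect_equal(fl, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # hand computation of the expected-occurrence criterion for the extreme
  z <- abs(100 - mean(v)) / sd(v)
  crit <- length(v) * 2 * pnorm(z, lower.tail = FALSE)
  expect_equal(round(crit, 2), 0.37)
  expect_lt(crit, 1)
  # all values within one sd are never flagged
  set.seed(1)
  expect_false(any(flag_outliers(runif(10, -1, 1))))
  # the flag agrees with the expected-occurrence criterion computed
  # independently, for every point of random samples
  for (i in 1:10) {
    vv <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
    zz <- abs(vv - mean(vv)) / sd(vv)
    expect_equal(flag_outliers(vv),
                 length(vv) * 2 * pnorm(zz, lower.tail = FALSE) < 1)
  }
  # m-dependence: the expected count grows with m, so duplicating the
  # sample un-flags a borderline point
  base <- c(1, 2, 3, 4, 6)
  expect_true(flag_outliers(base)[5])
  expect_false(any(flag_outliers(c(base, base))))
  expect_false(any(flag_outliers(rep(5, 5))))   # sd = 0 flags nothing
})

test_that("BLUEs equal hybrid means in balance and absorb replicate effects", {
  set.seed(2)
  hy <- paste0("h", 1:20)
  d <- data.frame(hybrid = rep(hy, 2), replicate = rep(1:2, each = 20),
                  value = rep(rnorm(20), 2) + rnorm(40, sd = 0.1))
  b <- fit_blues(d)
  mm <- tapply(d$value, d$hybrid, mean)
  expect_equal(unname(b[names(mm)]), as.vector(mm), tolerance = 1e-10)
  # an additive replicate shift is absorbed exactly in balance: hybrid
  # contrasts are unchanged (the marginal level moves by the rep average)
  d2 <- d
  d2$value[d2$replicate == 2] <- d2$value[d2$replicate == 2] + 1
  b2 <- fit_blues(d2)[names(b)]
  expect_equal(unname(b2 - mean(b2)), unname(b - mean(b)),
               tolerance = 1e-10)
  # single replicate, single block: plain hybrid means
  d3 <- d[d$replicate == 1, ]
  expect_equal(unname(fit_blues(d3)[hy]),
               as.vector(tapply(d3$value, d3$hybrid, mean)[hy]),
               tolerance = 1e-10)
})

test_that("REML recovers the block variance in the nested design", {
  set.seed(3)
  errs <- replicate(20, {
    hy <- paste0("h", 1:25)
    d <- expand.grid(hybrid = hy, replicate = 1:2, block = 1:4)
    d$value <- rep(rnorm(25, sd = 1), 8) +
      rnorm(8, sd = sqrt(0.5))[interaction(d$replicate, d$block)] +
      rnorm(nrow(d), sd = 0.5)
    fit <- lme4::lmer(value ~ hybrid + replicate + (1 | replicate:block),
                      data = transform(d, replicate = factor(replicate),
                                       block = factor(block)),
                      REML = TRUE)
    unlist(lme4::VarCorr(fit))[1]
  })
  expect_lt(abs(mean(errs) - 0.5) / 0.5, 0.3)
  # and the full mixed-model path produces BLUEs close to the true means
  set.seed(4)
  hy <- paste0("h", 1:15)
  mu <- rnorm(15)
  d <- expand.grid(hybrid = hy, replicate = 1:2, block = 1:2)
  d$value <- mu[as.integer(factor(d$hybrid))] + rnorm(nrow(d), sd = 0.2)
  b <- fit_blues(d)
  expect_gt(cor(b[hy], mu), 0.95)
})

test_that("trait-matrix assembly lays out P1 x experiment with key integrity", {
  blues <- list(L1_2015_A = c(h1 = 1, h2 = 2),
                L1_2015_B = c(h3 = 3, h4 = 4))
  p1 <- c(h1 = "p1", h2 = "p2", h3 = "p1", h4 = "p2")
  tm <- assemble_trait_matrix(blues, p1)
  expect_equal(dim(tm$values), c(2, 2))
  expect_equal(tm$values["p1", "L1_2015_A"], 1)
  expect_equal(tm$values["p1", "L1_2015_B"], 3)
  # a P1 absent from an experiment stays missing
  blues2 <- list(e1 = c(h1 = 1), e2 = c(h2 = 5))
  tm2 <- assemble_trait_matrix(blues2, p1)
  expect_true(is.na(tm2$values["p1", "e2"]))
  # duplicate (P1, experiment) keys are an error naming the P1
  blues3 <- list(e1 = c(h1 = 1, h3 = 2))
  expect_error(assemble_trait_matrix(blues3, p1), "p1")
})

test_that("parent genotype inference applies the stated dosage rules", {
  H <- rbind(hA = c(1, 2, 1, 1),
             hB = c(0, 2, 2, 1),
             hC = c(1, 1, 2, 2))
  colnames(H) <- paste0("s", 1:4)
  tof <- c(hA = "T1", hB = "T1", hC = "T1")
  out <- infer_parent_genotypes(H, tof)
  # s1: hB is 0 -> tester 0; hA het -> P1 = 2
  expect_equal(unname(out$tester["T1", "s1"]), 0)
  expect_equal(unname(out$P1["hA", "s1"]), 2)
  # s2: all homozygous 2 -> both parents 2
  expect_equal(unname(out$tester["T1", "s2"]), 2)
  expect_equal(unname(out$P1["hB", "s2"]), 2)
  # s3: no 0 present, hA het -> tester 2, P1 0
  expect_equal(unname(out$tester["T1", "s3"]), 2)
  expect_equal(unname(out$P1["hA", "s3"]), 0)
  # conflict trio (1, 0, 2) at one site: both parents missing there
  H2 <- rbind(hA = c(1), hB = c(0), hC = c(2))
  colnames(H2) <- "s1"
  out2 <- infer_parent_genotypes(H2, c(hA = "T1", hB = "T1", hC = "T1"))
  expect_true(is.na(out2$tester["T1", "s1"]))
  expect_true(is.na(out2$P1["hA", "s1"]))
  expect_equal(out2$conflicts, 1L)
  # a tester seen in a single hybrid is dropped
  out3 <- infer_parent_genotypes(rbind(H, hD = c(0, 1, 2, 0)),
                                 c(tof, hD = "T9"))
  expect_equal(out3$dropped, "hD")
})

test_that("inferred parents average back to the hybrid dosages", {
  set.seed(5)
  n_h <- 12; n_s <- 60
  testers <- paste0("T", rep(1:3, each = 4))
  t_geno <- matrix(sample(c(0, 2), 3 * n_s, replace = TRUE), 3,
                   dimnames = list(paste0("T", 1:3), NULL))
  p_geno <- matrix(sample(c(0, 2), n_h * n_s, replace = TRUE), n_h)
  H <- (p_geno + t_geno[testers, ]) / 2
  rownames(H) <- paste0("h", 1:n_h)
  colnames(H) <- colnames(t_geno) <- colnames(p_geno) <- paste0("s", 1:n_s)
  out <- infer_parent_genotypes(H, setNames(testers, rownames(H)))
  rebuilt <- (out$P1 + out$tester[testers, ]) / 2
  ok <- !is.na(rebuilt)
  expect_true(all(rebuilt[ok] == H[ok]))
  expect_gt(mean(ok), 0.95)
})

test_that("the VanRaden GRM matches the toy case and Hardy-Weinberg scaling", {
  M <- rbind(a = 0, b = 2)
  expect_equal(unname(vanraden_grm(M, p = 0.5)),
               rbind(c(2, -2), c(-2, 2)))
  # identical individuals give equal diagonal and off-diagonal entries
  M2 <- rbind(x = c(0, 1, 2, 1), y = c(0, 1, 2, 1), z = c(2, 1, 0, 1))
  G2 <- vanraden_grm(M2)
  expect_equal(G2["x", "x"], G2["y", "y"])
  expect_equal(G2["x", "y"], G2["x", "x"])
  # symmetric PSD
  set.seed(6)
  M3 <- matrix(rbinom(40 * 200, 2, 0.4), 40,
               dimnames = list(paste0("i", 1:40), NULL))
  G3 <- vanraden_grm(M3)
  expect_lt(max(abs(G3 - t(G3))), 1e-8)
  expect_gt(min(eigen(G3, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
  # mean diagonal ~ 1 under Hardy-Weinberg dosages
  diags <- replicate(10, {
    p <- runif(300, 0.1, 0.9)
    M <- sapply(p, function(pp) rbinom(50, 2, pp))
    mean(diag(vanraden_grm(M)))
  })
  expect_lt(abs(mean(diags) - 1), 3 * sd(diags) / sqrt(10) + 0.02)
})

test_that("GDD arithmetic applies the floors, cap and divisor", {
  w <- data.frame(date = as.Date("2020-05-01") + 0:2,
                  tmax = c(45, 90, 70), tmin = c(40, 40, 50))
  g <- compute_gdd_series(w)
  expect_equal(g$gdd, c(0, 18, 10))
  expect_equal(g$agdd, c(0, 18, 28))
  # literal (divisor = 1) variant for comparison
  g1 <- compute_gdd_series(w, divisor = 1)
  expect_equal(g1$gdd[1], 50)            # (50 + 50) - 50
  expect_warning(compute_gdd_series(
    data.frame(date = as.Date("2020-05-01") + 0:1,
               tmax = c(60, 50), tmin = c(50, 60))), "skipped")
})

test_that("stage partition is an interval lookup that conserves days", {
  stages <- data.frame(stage = c("a", "b", "c"),
                       agdd_threshold = c(0, 10, 20))
  st <- stage_partition(c(5, 15, 25), stages)
  expect_equal(as.character(st), c("a", "b", "c"))
  # a short season leaves the last stage empty
  st2 <- stage_partition(c(1, 2, 3), stages)
  expect_equal(sum(table(st2)), 3)
  expect_equal(unname(table(st2)["c"]), 0L)
  # full default table: 23 strictly increasing thresholds
  tab <- default_stage_table()
  expect_equal(nrow(tab), 23)
  expect_false(is.unsorted(tab$agdd_threshold, strictly = TRUE))
})

test_that("the weather EC builder yields the full 278-feature vector", {
  set.seed(7)
  days <- 150
  tmax <- runif(days, 55, 95)
  w <- data.frame(date = as.Date("2021-04-20") + seq_len(days) - 1,
                  tmax = tmax, tmin = tmax - runif(days, 5, 25),
                  precip = rexp(days, 2))
  for (v in paste0("wv", 1:11)) w[[v]] <- rnorm(days)
  w <- compute_gdd_series(w)
  ec <- build_weather_ecs(w, variables = paste0("wv", 1:11))
  expect_length(ec, 278)                  # (11 + 1) * 23 + 2
  expect_equal(unname(ec["APRE"]), sum(w$precip))
  expect_equal(unname(ec["AGDD"]), max(w$agdd))
  # a constant variable has all stage means equal where defined
  w$wv1 <- 3.3
  ec2 <- build_weather_ecs(w, variables = paste0("wv", 1:11))
  v1 <- ec2[grep("^wv1_", names(ec2))]
  expect_true(all(v1[!is.na(v1)] == 3.3))
})

test_that("eigenfeatures reconstruct covariance and stay orthogonal", {
  set.seed(8)
  X <- matrix(rnorm(12 * 30), 12, 30)
  F_ <- ec_eigenfeatures(X, n_components = 11)
  # Gram identity: with all components the feature Gram equals the
  # standardised-row covariance
  sds <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, colMeans(X), "-"), 2, sds, "/")
  expect_equal(tcrossprod(F_), tcrossprod(Xs) / (ncol(X) - 1),
               tolerance = 1e-8, ignore_attr = TRUE)
  cp <- crossprod(F_)
  expect_lt(max(abs(cp - diag(diag(cp)))), 1e-8)
  # identical rows: one constant component, the rest vanish
  X2 <- matrix(rep(rnorm(10), each = 5), 5)
  F2 <- ec_eigenfeatures(X2, n_components = 4)
  expect_lt(max(abs(F2[, -1])), 1e-6)
  expect_equal(var(as.vector(F2[, 1])), 0, tolerance = 1e-10)
  # PSD similarity input is eigendecomposed directly
  K <- simulate_kinship(15, 5, seed = 9)
  FK <- ec_eigenfeatures(K, n_components = 15)
  expect_equal(tcrossprod(FK), unclass(K), tolerance = 1e-8,
               ignore_attr = TRUE)
})
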