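# assembles a feature matrix directly (no fNIRS simulation): numeric group
# effects planted per column as requested
mkFeatures <- function(n = 34, effects = c(ldlpfc_nvc_beta = 2,
                                           ceev_ratio = 2, wd_ldp = 2),
                       seed = 1) {
  set.seed(seed)
  nC <- ceiling(n / 2); nM <- n - nC
  lab <- factor(c(rep("CN", nC), rep("MCI", nM)), levels = c("CN", "MCI"))
  cols <- c("ldlpfc_nvc_beta", "ceev_ratio", "wd_ldp", "d_ldp", "d_bar",
            "wd_bar", "age")
  df <- as.data.frame(setNames(lapply(cols, function(cc) {
    delta <- if (cc %in% names(effects)) effects[[cc]] else 0
    rnorm(n) - delta * (as.integer(lab) - 1)   # MCI shifted downward
  }), cols))
  df$sex <- factor(sample(c("F", "M"), n, TRUE), levels = c("F", "M"))
  df$hypertension <- factor(runif(n) < 0.4, levels = c(FALSE, TRUE))
  df$depression_prior <- factor(runif(n) < 0.2, levels = c(FALSE, TRUE))
  df$label <- lab
  rownames(df) <- sprintf("S%02d", seq_len(n))
  df
}

test_that("feature assembly joins by subject and drops incomplete cases", {
  cfg <- simConfig(nCn = 3, nMci = 3, seed = 2)
  coh <- simulateCohort(cfg)
  nvc <- data.frame(subject_id = coh$subject_id, ldlpfc_beta = 1:6)
  fc <- data.frame(subject_id = coh$subject_id, d_bar = 0.5, wd_bar = 0.4,
                   d_ldp = 0.6, wd_ldp = 0.3)
  ev <- data.frame(subject_id = coh$subject_id[-2], ceev_ratio = 10)
  expect_message(f <- assembleFeatures(nvc, fc, ev, coh), "S02")
  expect_equal(nrow(f), 5)
  expect_false("S02" %in% rownames(f))
  expect_s3_class(f$sex, "factor")
  # order independence of the join
  expect_message(f2 <- assembleFeatures(nvc[sample(6), ], fc[sample(6), ],
                                        ev[sample(5), ], coh[sample(6), ]))
  expect_equal(f, f2, ignore_attr = TRUE)
  # reduced feature set without the EV stage
  fNoEv <- assembleFeatures(nvc, fc, NULL, coh)
  expect_false("ceev_ratio" %in% names(fNoEv))
})

test_that("LOOCV importance finds a label-determining feature", {
  set.seed(91)
  wins <- vapply(1:10, function(k) {
    f <- mkFeatures(n = 60, effects = c(ldlpfc_nvc_beta = 50), seed = 100 + k)
    imp <- loocvImportance(f, nTrees = 150, seed = k)
    names(which.max(imp)) == "ldlpfc_nvc_beta"
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("pure-noise features have no stable importance winner", {
  # exchangeable numeric noise features (Gini importance is not comparable
  # across feature types, so the null check uses a homogeneous set)
  set.seed(92)
  imps <- vapply(1:10, function(k) {
    f <- mkFeatures(n = 40, effects = c(), seed = 200 + k)
    f <- f[, c("ldlpfc_nvc_beta", "ceev_ratio", "wd_ldp", "d_ldp", "d_bar",
               "wd_bar", "age", "label")]
    loocvImportance(f, nTrees = 150, seed = k)
  }, numeric(7))
  m <- rowMeans(imps)
  expect_lt(max(m) / min(m), 2)
})

test_that("per-fold importances are normalized and reproducible", {
  f <- mkFeatures(n = 20, seed = 3)
  imp <- loocvImportance(f, nTrees = 100, seed = 5)
  folds <- attr(imp, "folds")
  sums <- rowSums(folds)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-6))
  imp2 <- loocvImportance(f, nTrees = 100, seed = 5)
  expect_equal(imp, imp2)
})

test_that("top-k selection orders by importance with a stable tie-break", {
  imp <- c(a = 0.4, b = 0.3, c = 0.1, d = 0.1, e = 0.1)
  expect_equal(selectTopK(imp, 3), c("a", "b", "c"))
  expect_equal(selectTopK(imp, 5), c("a", "b", "c", "d", "e"))
  expect_error(selectTopK(imp, 6), "exceeds")
  # planted-effect end-to-end selection lives in the acceptance suite
})

test_that("split evaluation computes the classification metrics", {
  # perfectly separable features
  f <- mkFeatures(n = 24, effects = c(ldlpfc_nvc_beta = 100), seed = 4)
  res <- evaluateSplit(f, "ldlpfc_nvc_beta", seed = 1)
  expect_equal(res$accuracy, 1)
  expect_equal(res$f1, 1)
  # harmonic-mean arithmetic
  p <- 0.8; r <- 0.6
  expect_equal(2 * p * r / (p + r), 0.6857, tolerance = 1e-4)
  # label-shuffled features: mean accuracy compatible with chance
  set.seed(93)
  accs <- vapply(1:40, function(k) {
    f0 <- mkFeatures(n = 20, effects = c(), seed = 300 + k)
    evaluateSplit(f0, c("ldlpfc_nvc_beta", "age"), nTrees = 100,
                  seed = k)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 3 * sd(accs) / sqrt(40))
})

test_that("repeated splits are reproducible and degenerate correctly", {
  f <- mkFeatures(n = 24, effects = c(ldlpfc_nvc_beta = 100), seed = 6)
  r1 <- repeatedSplits(f, "ldlpfc_nvc_beta", nRuns = 12, nTrees = 100, seed = 2)
  r2 <- repeatedSplits(f, "ldlpfc_nvc_beta", nRuns = 12, nTrees = 100, seed = 2)
  expect_equal(r1$mean_accuracy, r2$mean_accuracy)
  expect_equal(r1$sd_accuracy, r2$sd_accuracy)
  expect_equal(r1$mean_accuracy, 1)
  expect_equal(r1$sd_accuracy, 0)
  expect_equal(r1$n_failed, 0)
})

test_that("standardization parameters come from training folds only", {
  f <- mkFeatures(n = 20, seed = 7)
  x <- f[, setdiff(names(f), "label")]
  tr <- 1:16
  pp1 <- mcimark:::.fitPreproc(x[tr, ])
  # corrupting held-out rows cannot change the training-fold transform
  xCorrupt <- x
  xCorrupt$age[17:20] <- xCorrupt$age[17:20] * 100
  pp2 <- mcimark:::.fitPreproc(xCorrupt[tr, ])
  expect_identical(pp1, pp2)
  enc1 <- mcimark:::.applyPreproc(pp1, x[tr, ])
  # training-fold numeric columns are standardized to mean 0 / unit SD
  expect_lt(max(abs(vapply(enc1[pp1$num], mean, numeric(1)))), 1e-10)
  expect_lt(max(abs(vapply(enc1[pp1$num], sd, numeric(1)) - 1)), 1e-10)
  # one-hot encoding of categoricals
  expect_true(all(c("sex.F", "sex.M") %in% names(enc1)))
  expect_true(all(enc1$sex.F + enc1$sex.M == 1))
})
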