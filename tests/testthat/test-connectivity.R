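# helpers building FC-branch HbT series directly
hbtSeries <- function(M, fs = 3.9, labels = paste0("ch", seq_len(nrow(M)))) {
  s <- makeSeries(M / 2, M / 2, fs = fs, labels = labels)
  s@branch <- "fc"
  totalHemoglobin(s)
}
oneBlockDesign <- function() taskDesign(order = "2b", leadInS = 0, seed = 1)

test_that("block correlation windows the block and correlates channels", {
  set.seed(51)
  des <- oneBlockDesign()
  n <- ceiling(designDuration(des) * 3.9)
  base <- rnorm(n)
  M <- rbind(base, base, rnorm(n))
  s <- hbtSeries(M)
  bc <- blockCorrelation(s, des, "2b")
  expect_equal(diff(bc$window) + 1, floor(72 * 3.9))   # ~281 samples
  expect_equal(unname(diag(bc$r)), rep(1, 3))          # self-correlation
  expect_equal(bc$r[1, 2], 1)                          # identical channels
  expect_lt(abs(bc$r[1, 3]), 0.5)
  expect_error(blockCorrelation(s, des, "1b"), "no such block")
  short <- hbtSeries(M[, 1:100])
  expect_error(blockCorrelation(short, des, "2b"), "beyond")
})

test_that("independent channels have the null correlation distribution", {
  set.seed(52)
  des <- oneBlockDesign()
  n <- ceiling(designDuration(des) * 3.9)
  rs <- replicate(400, {
    s <- hbtSeries(rbind(rnorm(n), rnorm(n)))
    blockCorrelation(s, des, "2b")$r[1, 2]
  })
  nw <- floor(72 * 3.9)
  expect_lt(abs(mean(rs)), 3 * 1 / sqrt(nw - 1) / sqrt(400) + 0.01)
  expect_lt(abs(sd(rs) - 1 / sqrt(nw - 1)), 0.015)
})

test_that("surrogate thresholding keeps true edges and drops sign/chance", {
  set.seed(53)
  des <- oneBlockDesign()
  n <- ceiling(designDuration(des) * 3.9)
  base <- rnorm(n)
  # perfectly coupled pair retained at r* ~ 1; anti-correlated pair zeroed
  M <- rbind(base, base + 1e-6 * rnorm(n), -base)
  bc <- blockCorrelation(hbtSeries(M), des, "2b")
  g <- surrogateThreshold(bc, nSurr = 100)
  expect_gt(rStar(g)[1, 2], 0.999)
  expect_equal(rStar(g)[1, 3], 0)      # negative r -> 0 regardless of p
  expect_equal(rStar(g)[2, 3], 0)
  expect_true(isSymmetric(rStar(g)))
  expect_equal(unname(diag(rStar(g))), rep(0, 3))
  # too few surrogates cannot resolve p < alpha
  expect_error(surrogateThreshold(bc, alpha = 0.05, nSurr = 10), "resolve")
})

test_that("surrogate retention under independence is calibrated to alpha", {
  set.seed(54)
  des <- oneBlockDesign()
  n <- ceiling(designDuration(des) * 3.9)
  kept <- replicate(400, {
    bc <- blockCorrelation(hbtSeries(rbind(rnorm(n), rnorm(n))), des, "2b")
    rStar(surrogateThreshold(bc, nSurr = 60))[1, 2] > 0
  })
  mc <- 3 * sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(kept) - 0.05), mc + 0.01)
})

test_that("graph metrics match hand enumeration and the brute-force oracle", {
  m <- smallMontage()
  # 4-node example: edges (1,2) = 0.5, (2,3) = 0.25
  r <- matrix(0, 4, 4, dimnames = list(paste0("n", 1:4), paste0("n", 1:4)))
  r[1, 2] <- r[2, 1] <- 0.5
  r[2, 3] <- r[3, 2] <- 0.25
  gm <- graphMetrics(r, m)
  expect_equal(gm$perNode$degree, c(1, 2, 1, 0))
  expect_equal(gm$dBar, mean(c(1, 2, 1, 0) / 3))
  expect_equal(gm$dBar, 1 / 3)
  # weighted: strengths (.5, .75, .25, 0) / ((N-1) * max = 1.5)
  expect_equal(gm$perNode$normStrength, c(0.5, 0.75, 0.25, 0) / 1.5)
  expect_equal(gm$wdBar, mean(c(0.5, 0.75, 0.25, 0) / 1.5))
  # complete graph with constant weight c -> both normalized metrics 1
  rc <- matrix(0.4, 5, 5); diag(rc) <- 0
  gmc <- graphMetrics(rc, m)
  expect_equal(gmc$dBar, 1)
  expect_equal(gmc$wdBar, 1)
  # empty graph -> all zero
  gm0 <- graphMetrics(matrix(0, 4, 4), m)
  expect_equal(gm0$dBar, 0)
  expect_equal(gm0$wdBar, 0)
  expect_error(graphMetrics(matrix(0, 1, 1), m), "2 nodes")
  # brute-force equivalence on random small graphs (N <= 6), including the
  # LDLPFC node subset
  set.seed(55)
  for (rep in 1:40) {
    N <- sample(2:6, 1)
    r <- matrix(0, N, N)
    nodes <- c(ldlpfcChannels(m), paste0("x", 1:3))[sample(6, N)]
    dimnames(r) <- list(nodes, nodes)
    for (i in seq_len(N - 1)) for (j in (i + 1):N)
      if (runif(1) < 0.5) r[i, j] <- r[j, i] <- round(runif(1), 2)
    gm <- graphMetrics(r, m)
    or <- bruteForceMetrics(r, ldlpfcChannels(m))
    expect_equal(gm$dBar, or$dBar)
    expect_equal(gm$wdBar, or$wdBar)
    expect_equal(gm$dLdp, or$dLdp)
    expect_equal(gm$wdLdp, or$wdLdp)
    expect_equal(gm$perNode$degree, or$degree)
    expect_equal(gm$perNode$strength, or$strength, tolerance = 1e-12)
    # all normalized metrics bounded in [0, 1]
    expect_true(all(gm$perNode$normDegree >= 0 & gm$perNode$normDegree <= 1))
    expect_true(all(gm$perNode$normStrength >= 0 & gm$perNode$normStrength <= 1))
  }
})

test_that("the alternative weighted normalization stays in [0, 1]", {
  m <- smallMontage()
  r <- matrix(0, 3, 3); r[1, 2] <- r[2, 1] <- 0.9; r[2, 3] <- r[3, 2] <- 0.3
  gm <- graphMetrics(r, m, weightedNorm = "possible")
  expect_equal(gm$perNode$normStrength, c(0.9, 1.2, 0.3) / 2)
  expect_true(all(gm$perNode$normStrength <= 1))
})

test_that("task averaging is the arithmetic mean over blocks", {
  df <- data.frame(condition = conditionLevels(),
                   dBar = c(0.2, 0.4, 0.6, 0.8),
                   wdBar = 0.5, dLdp = c(0.1, 0.2, 0.3, 0.4), wdLdp = 0.25)
  ta <- taskAverage(df)
  expect_equal(unname(ta["dBar"]), 0.5)
  expect_equal(unname(ta["wdBar"]), 0.5)
  expect_equal(unname(ta["dLdp"]), 0.25)
  # identical per-block values pass through
  df2 <- df; df2$dBar <- 0.7
  expect_equal(unname(taskAverage(df2)["dBar"]), 0.7)
  # missing block: available-mean
  df3 <- df; df3$dBar[2] <- NA
  expect_equal(unname(taskAverage(df3)["dBar"]), mean(c(0.2, 0.6, 0.8)))
})

test_that("Fisher averaging works on the atanh scale", {
  mkGraph <- function(r12) {
    r <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
    r[1, 2] <- r[2, 1] <- r12
    new("ConnectivityGraph", condition = "2b", nodes = c("a", "b"),
        rStar = r, zMatrix = atanh(pmin(r, 1 - 1e-12)))
  }
  # all zero -> zero
  f0 <- fisherAverage(list(mkGraph(0), mkGraph(0)))
  expect_equal(max(abs(f0$z)), 0)
  # constant 0.5 -> back-transformed 0.5
  f5 <- fisherAverage(list(mkGraph(0.5), mkGraph(0.5)))
  expect_equal(f5$r[1, 2], 0.5, tolerance = 1e-12)
  # {0.3, 0.9}: tanh(mean(atanh)) != arithmetic mean 0.6
  f39 <- fisherAverage(list(mkGraph(0.3), mkGraph(0.9)))
  oracle <- tanh((atanh(0.3) + atanh(0.9)) / 2)
  expect_equal(f39$r[1, 2], oracle, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(oracle, 0.6, tolerance = 1e-3)))
  # mismatched node sets are an error
  g2 <- mkGraph(0.2); g2@nodes <- c("a", "c")
  expect_error(fisherAverage(list(mkGraph(0.1), g2)), "node set")
})
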