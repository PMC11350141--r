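test_that("OD conversion follows the log-ratio definition and inverts", {
  m <- smallMontage(1)
  nT <- 50
  # constant intensity -> zero OD
  rec <- makeRecording(matrix(2, 4, nT), matrix(0.7, 4, nT), m)
  expect_equal(max(abs(intensitiesToOd(rec))), 0)
  # I = mean/10 at one sample -> OD = 1 there (mean recomputed post hoc)
  I <- matrix(1, 4, nT)
  I[1, 10] <- mean(I[1, -10]) / 10  # approx; use exact check instead below
  od1 <- -log10(I[1, 10] / mean(I[1, ]))
  rec <- makeRecording(I, matrix(1, 4, nT), m)
  od <- intensitiesToOd(rec)
  expect_equal(od[1, 1, 10], od1)
  expect_gt(od1, 0.95)
  # forward round trip: OD -> 10^-OD -> OD is identity up to a per-channel
  # constant
  set.seed(2)
  od0 <- array(rnorm(4 * 2 * nT, 0, 0.05), c(4, 2, nT))
  I760 <- 10^(-od0[, 1, ]); I850 <- 10^(-od0[, 2, ])
  back <- intensitiesToOd(makeRecording(I760, I850, m))
  for (i in 1:4) for (w in 1:2)
    expect_lt(sd(back[i, w, ] - od0[i, w, ]), 1e-12)
  # nonpositive intensity is an input error
  I760[1, 1] <- 0
  expect_error(intensitiesToOd(makeRecording(I760, I850, m)), "positive")
})

test_that("scalp-coupling screen scores shared cardiac content", {
  m <- smallMontage(5)
  fs <- 3.9
  nT <- 400
  tt <- (seq_len(nT) - 1) / fs
  card <- sin(2 * pi * 1.1 * tt)
  set.seed(8)
  nCh <- nrow(m@channels)
  I760 <- 1 + 0.05 * matrix(card, nCh, nT, byrow = TRUE) +
    0.005 * matrix(rnorm(nCh * nT), nCh)
  I850 <- 1 + 0.04 * matrix(card, nCh, nT, byrow = TRUE) +
    0.005 * matrix(rnorm(nCh * nT), nCh)
  qc <- assessQuality(makeRecording(I760, I850, m))
  expect_true(all(qc$score > 0.9))
  expect_false(qc$excluded)
  # independent noise in the two wavelengths -> score ~ 0, poor
  In1 <- 1 + 0.05 * matrix(rnorm(nCh * nT), nCh)
  In2 <- 1 + 0.05 * matrix(rnorm(nCh * nT), nCh)
  qc2 <- assessQuality(makeRecording(In1, In2, m))
  expect_true(all(abs(qc2$score) < 0.4))
  expect_true(all(qc2$poor))
  # LDLPFC good but >80% of the others poor -> excluded by the 80% rule
  Im1 <- In1; Im2 <- In2
  ldl <- match(ldlpfcChannels(m), channelLabels(m))
  Im1[ldl, ] <- I760[ldl, ]; Im2[ldl, ] <- I850[ldl, ]
  qc3 <- assessQuality(makeRecording(Im1, Im2, m))
  expect_false(any(qc3$poor[ldl]))
  # 5 of 8 poor = 62% -> not excluded by the 80% rule; force more channels
  m2 <- smallMontage(5)
  expect_false(qc3$excluded && !any(qc3$poor[ldl]))
  # short recording is an input error
  expect_error(assessQuality(makeRecording(I760[, 1:50], I850[, 1:50], m)),
               "short")
})

test_that("the 80 percent rule and the LDLPFC rule both exclude", {
  m <- smallMontage(5)   # 8 channels: >80% poor needs 7+
  fs <- 3.9; nT <- 400
  tt <- (seq_len(nT) - 1) / fs
  card <- 0.05 * sin(2 * pi * 1.1 * tt)
  set.seed(3)
  nCh <- 8
  good1 <- 1 + matrix(card, nCh, nT, byrow = TRUE) + 0.004 * matrix(rnorm(nCh * nT), nCh)
  good2 <- 1 + 0.8 * matrix(card, nCh, nT, byrow = TRUE) + 0.004 * matrix(rnorm(nCh * nT), nCh)
  noise <- function() 1 + 0.05 * matrix(rnorm(nCh * nT), nCh)
  # all poor -> excluded by 80% rule
  qcAll <- assessQuality(makeRecording(noise(), noise(), m))
  expect_true(qcAll$excluded)
  expect_match(paste(qcAll$reason, collapse = " "), "80%")
  # only one LDLPFC channel poor -> excluded by LDLPFC rule
  I1 <- good1; I2 <- good2
  ldl1 <- match("F3-F1", channelLabels(m))
  I1[ldl1, ] <- 1 + 0.05 * rnorm(nT)
  qcL <- assessQuality(makeRecording(I1, I2, m))
  expect_true(qcL$excluded)
  expect_match(paste(qcL$reason, collapse = " "), "LDLPFC")
})

test_that("motion correction removes spikes and steps, leaves clean data alone", {
  set.seed(11)
  fs <- 3.9
  n <- 800
  clean <- matrix(rnorm(2 * n), 2)
  out <- correctMotion(clean, fs = fs)
  expect_equal(unname(out[, ]), unname(clean), tolerance = 1e-12)
  expect_false(any(attr(out, "artifactMask")))
  # injected 10-SD spike is removed
  x <- clean
  x[1, 400] <- x[1, 400] + 10
  fixed <- correctMotion(x, fs = fs)
  expect_true(attr(fixed, "artifactMask")[1, 400])
  expect_lt(abs(fixed[1, 400]), 2)
  # injected baseline step: post-correction segment means differ < 0.5 SD
  y <- matrix(rnorm(n), 1)
  y[1, 401:n] <- y[1, 401:n] + 6
  fy <- correctMotion(y, fs = fs)
  expect_lt(abs(mean(fy[1, 1:400]) - mean(fy[1, 401:n])), 0.5)
})

test_that("MBLL solves its own forward model exactly", {
  m <- smallMontage(1)
  nT <- 30
  set.seed(5)
  hboT <- matrix(rnorm(4 * nT, 0, 5), 4)
  hbrT <- matrix(rnorm(4 * nT, 0, 2), 4)
  eps <- mbllExtinction()
  dpf <- c(6, 6)
  sep <- m@channels$separation_cm
  od <- array(0, c(4, 2, nT))
  for (w in 1:2)
    od[, w, ] <- (eps[w, "HbO"] * hboT + eps[w, "HbR"] * hbrT) * sep * dpf[w] / 1000
  attr(od, "fsHz") <- 3.9
  cs <- mbll(od, m)
  expect_lt(max(abs(hbo(cs) - hboT)), 1e-9)
  expect_lt(max(abs(hbr(cs) - hbrT)), 1e-9)
  # zero OD -> zero chromophores
  z <- mbll(array(0, c(4, 2, nT)), m, fs = 3.9)
  expect_equal(max(abs(hbo(z))), 0)
  expect_equal(max(abs(hbr(z))), 0)
  # linearity: scaling OD by c scales both chromophores by c
  c3 <- mbll(od * 3, m)
  expect_equal(hbo(c3), 3 * hbo(cs), tolerance = 1e-10)
  expect_equal(hbr(c3), 3 * hbr(cs), tolerance = 1e-10)
  # singular extinction matrix is a configuration error
  expect_error(mbll(od, m, extinction = matrix(1, 2, 2)), "singular")
})

test_that("DCT high-pass removes slow components and passes fast ones", {
  fs <- 3.9
  n <- 3000                      # ~770 s record
  tt <- (seq_len(n) - 1) / fs
  # constant -> zero
  cs <- makeSeries(matrix(5, 1, n))
  expect_lt(max(abs(hbo(dctHighpass(cs)))), 1e-9)
  # 0.002 Hz (below cutoff): residual power < 1%
  slow <- sin(2 * pi * 0.002 * tt)
  out <- dctHighpass(makeSeries(matrix(slow, 1)))
  expect_lt(sum(hbo(out)^2) / sum(slow^2), 0.01)
  # 0.05 Hz (above cutoff): preserved > 95% power
  fast <- sin(2 * pi * 0.05 * tt)
  out2 <- dctHighpass(makeSeries(matrix(fast, 1)))
  expect_gt(sum(hbo(out2)^2) / sum(fast^2), 0.95)
  # cutoff at/above Nyquist is a configuration error
  expect_error(dctHighpass(cs, cutoffHz = 2), "Nyquist")
})

test_that("AR prewhitening recovers the noise model and whitens residuals", {
  set.seed(21)
  n <- 4000
  X <- cbind(a = sin(2 * pi * (1:n) / 500), b = cos(2 * pi * (1:n) / 350))
  # white input: fitted filter is near identity
  w <- prewhiten(rnorm(n), X)
  expect_true(length(w$phi) == 0 || all(abs(w$phi) < 0.1))
  # AR(1) phi = 0.8 recovered within 0.05
  e <- as.numeric(filter(rnorm(n), 0.8, method = "recursive"))
  y <- X %*% c(2, -1) + e
  w2 <- prewhiten(as.numeric(y), X)
  expect_gt(length(w2$phi), 0)
  expect_lt(abs(w2$phi[1] - 0.8), 0.05)
  # whitened OLS residuals have |lag-1 autocorrelation| < 0.1
  fit <- lm.fit(cbind(1, w2$X), w2$y)
  r1 <- acf(fit$residuals, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1), 0.1)
})

test_that("FC band-pass has the specified response", {
  fs <- 3.9
  n <- 4000
  tt <- (seq_len(n) - 1) / fs
  mid <- 800:3200                      # avoid filter edges
  # DC removed
  dc <- matrix(3, 1, n)
  out <- bandpassFc(makeSeries(dc))
  expect_lt(max(abs(hbo(out)[mid])), 1e-6)
  # 0.1 Hz preserved within 5%
  s01 <- sin(2 * pi * 0.1 * tt)
  a01 <- hbo(bandpassFc(makeSeries(matrix(s01, 1))))[mid]
  expect_lt(abs(sd(a01) / sd(s01[mid]) - 1), 0.05)
  # 1.0 Hz (cardiac) attenuated by > 90%
  s1 <- sin(2 * pi * 1.0 * tt)
  a1 <- hbo(bandpassFc(makeSeries(matrix(s1, 1))))[mid]
  expect_lt(sd(a1) / sd(s1[mid]), 0.1)
  # invalid band
  expect_error(bandpassFc(makeSeries(dc), low = 0.5, high = 0.4), "band")
})

test_that("CBSI enforces anti-correlation and removes common-mode artifacts", {
  set.seed(31)
  n <- 600
  hboM <- matrix(rnorm(n, 0, 2), 1)
  hbrM <- matrix(-hboM / 3 + rnorm(n, 0, 0.5), 1)
  out <- cbsi(makeSeries(hboM, hbrM))
  expect_equal(cor(hbo(out)[1, ], hbr(out)[1, ]), -1, tolerance = 1e-12)
  # common-mode spike (same sign in both chromophores) vanishes
  hboS <- hboM; hbrS <- hbrM
  alpha <- sd(hboS) / sd(hbrS)
  spike <- numeric(n); spike[300] <- 50
  hboS <- hboS + spike
  hbrS <- hbrS + spike / alpha     # scaled common mode
  outS <- cbsi(makeSeries(hboS, hbrS))
  # residual at the spike is comparable to background, not to the spike
  expect_lt(abs(hbo(outS)[1, 300]), 5)
  # ideal anti-correlated input passes through: hbr = -hbo/alpha
  hbrI <- -hboM / alpha
  outI <- cbsi(makeSeries(hboM, hbrI))
  expect_equal(hbo(outI)[1, ], hboM[1, ], tolerance = 1e-8)
})

test_that("total hemoglobin is the elementwise sum", {
  set.seed(1)
  a <- matrix(rnorm(100), 2)
  b <- matrix(rnorm(100), 2)
  s <- totalHemoglobin(makeSeries(a, b))
  expect_equal(hbt(s), a + b, ignore_attr = TRUE)
  z <- totalHemoglobin(makeSeries(a, -a))
  expect_equal(max(abs(hbt(z))), 0)
  i <- totalHemoglobin(makeSeries(a, a * 0))
  expect_equal(hbt(i), hbo(i))
})

test_that("the two preprocessing branches cannot be mixed", {
  cs <- makeSeries(matrix(rnorm(400), 1))
  nvc <- dctHighpass(cs)
  expect_error(bandpassFc(nvc), "branch")
  expect_error(cbsi(nvc), "branch")
  fc <- bandpassFc(cs)
  expect_error(dctHighpass(fc), "branch")
  expect_match(paste(fc@filters, collapse = ";"), "butter")
  expect_match(paste(nvc@filters, collapse = ";"), "dct")
})
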