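test_that("cohort generation is balanced, age-truncated and reproducible", {
  cfg <- simConfig(nCn = 4, nMci = 4, seed = 7)
  coh <- simulateCohort(cfg)
  expect_equal(nrow(coh), 8)
  expect_equal(as.vector(table(coh$group)), c(4, 4))
  expect_true(all(coh$age >= 50))
  expect_true(all(is.na(coh$fazekas[coh$group == "CN"])))
  expect_true(all(coh$fazekas[coh$group == "MCI"] %in% 0:3))
  expect_identical(coh, simulateCohort(cfg))
  big <- simulateCohort(simConfig(nCn = 200, nMci = 200, seed = 1))
  expect_true(all(big$age >= 50))
})

test_that("sessions are deterministic under a fixed seed", {
  cfg <- simConfig(nCn = 1, nMci = 1, seed = 3)
  s <- cnSubject(cfg)
  des <- taskDesign(order = c("0b_1", "2b"), seed = 1)
  r1 <- simulateFnirsSession(s, des, cfg, smallMontage(), seed = 9)
  r2 <- simulateFnirsSession(s, des, cfg, smallMontage(), seed = 9)
  expect_identical(r1@intensities, r2@intensities)
})

test_that("a silent forward model yields constant intensities", {
  cfg <- quietConfig(amplitude = zeroCondAmps(0))
  s <- cnSubject(cfg)
  des <- taskDesign(order = c("0b_1", "2b"), seed = 1)
  rec <- simulateFnirsSession(s, des, cfg, smallMontage(), seed = 2)
  expect_lt(diff(range(rec@intensities)), 1e-12)
})

test_that("planted amplitudes survive the analysis chain exactly when noiseless", {
  cfg <- quietConfig()
  m <- smallMontage()
  des <- defaultTaskDesign()
  for (s in list(cnSubject(cfg), mciSubject(cfg))) {
    rec <- simulateFnirsSession(s, des, cfg, m, seed = 5)
    nvc <- dctHighpass(mbll(intensitiesToOd(rec), m))
    b <- firstLevel(nvc, des, s$subject_id)
    amp <- rec@groundTruth$amplitude
    bh <- b[b$chromophore == "HbO", ]
    for (i in seq_len(nrow(bh))) {
      a <- amp[bh$channel[i], bh$condition[i]]
      expect_lt(abs(bh$beta[i] - a) / abs(a), 1e-6)
    }
  }
})

test_that("coupling weight w yields pairwise correlation sqrt(w1 w2)", {
  # single global latent (sigma = Inf): closed form sqrt(w1 w2) = w for
  # equal weights; checked against the simulated HbO ground truth
  des <- taskDesign(order = c("0b_1", "2b"), seed = 1)
  m <- smallMontage()
  for (w in c(0, 0.49, 0.81)) {
    cfg <- quietConfig(amplitude = zeroCondAmps(0),
                       fcCoupling = flatCoupling(w), fcSigmaCm = Inf)
    cfg$noise$whiteSd <- 1; cfg$noise$ar <- 0.3
    rs <- replicate(30, {
      s <- cnSubject(cfg)
      rec <- simulateFnirsSession(s, des, cfg, m)
      gt <- rec@groundTruth$hbo
      cor(gt[1, ], gt[4, ])
    })
    expect_lt(abs(mean(rs) - w), 0.06)
  }
})

test_that("planted coupling raises expected HbT correlation monotonically", {
  des <- taskDesign(order = c("2b"), seed = 1)
  m <- smallMontage()
  means <- vapply(c(0.1, 0.5, 0.9), function(w) {
    cfg <- quietConfig(amplitude = zeroCondAmps(0),
                       fcCoupling = flatCoupling(w), fcSigmaCm = Inf)
    cfg$noise$whiteSd <- 1; cfg$noise$ar <- 0.3
    mean(replicate(20, {
      rec <- simulateFnirsSession(cnSubject(cfg), des, cfg, m)
      gt <- rec@groundTruth$hbo
      r <- cor(t(gt)); mean(r[upper.tri(r)])
    }))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("behavioral generator honors degenerate and binomial regimes", {
  cfg <- simConfig(seed = 2)
  # degenerate: perfect hits, no false alarms
  beh <- cfg$behavior
  for (g in names(beh)) for (cc in names(beh[[g]])) {
    beh[[g]][[cc]]["hit_p"] <- 1; beh[[g]][[cc]]["fa_p"] <- 0
  }
  cfgd <- simConfig(seed = 2, behavior = beh)
  s <- cnSubject(cfgd)
  des <- defaultTaskDesign()
  tr <- simulateBehavior(s, des, cfgd, seed = 1)
  expect_true(all(tr$responded[tr$is_target]))
  expect_false(any(tr$responded[!tr$is_target]))
  # determinism
  tr2 <- simulateBehavior(s, des, cfgd, seed = 1)
  expect_identical(tr, tr2)
  # binomial oracle: ~1000 targets at hit_p = 0.8
  for (g in names(beh)) for (cc in names(beh[[g]])) beh[[g]][[cc]]["hit_p"] <- 0.8
  cfgb <- simConfig(seed = 2, behavior = beh)
  fake <- list(trials = data.frame(condition = "2b",
                                   onset_s = seq_len(1000),
                                   letter = "A", is_target = TRUE))
  trb <- simulateBehavior(s, fake, cfgb, seed = 4)
  phat <- mean(trb$responded)
  expect_lt(abs(phat - 0.8), 3 * sqrt(0.8 * 0.2 / 1000))
})

test_that("EV generator plants the configured CEEV fraction", {
  cfg <- simConfig(seed = 6)
  cfg$ev$subjectSdLogit <- 0
  s <- mciSubject(cfg)
  # degenerate: no CEEVs at all
  cfg0 <- cfg; cfg0$ev$ceevFraction <- c(CN = 0, MCI = 0)
  s0 <- simulateEvSample(s, cfg0, nEvents = 5000, seed = 1)
  expect_equal(sum(s0$stained$true_label == "ceev"), 0)
  # binomial oracle at f = 0.12 among endothelial events
  cfg$ev$ceevFraction <- c(CN = 0.12, MCI = 0.12)
  sv <- simulateEvSample(s, cfg, nEvents = 50000, seed = 2)
  endo <- sv$stained$true_label %in% c("ceev", "eev")
  f <- mean(sv$stained$true_label[endo] == "ceev")
  nE <- sum(endo)
  expect_lt(abs(f - 0.12), 3 * sqrt(0.12 * 0.88 / nE))
  # acquisition volume = 1.5 uL/min x 120 s = 3 uL
  expect_equal(sv$acquisition$volume_ul, 3)
  expect_identical(sort(names(sv$fmo)),
                   sort(c("endo_ch", "lymph_platelet_ch", "mal_ch")))
})
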