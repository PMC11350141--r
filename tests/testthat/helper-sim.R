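# shared fixtures, all generated in code

# reduced frontal montage: the three LDLPFC channels plus a ring of others;
# used where problem size matters and the full 48-channel cap is not the
# object under test
smallMontage <- function(nOther = 3) {
  stopifnot(nOther >= 1, nOther <= 5)
  src <- c("F3", "F3", "F3", "Fz", "F4", "AF3", "FC1", "F7")
  det <- c("F5", "F1", "FC3", "F1", "F6", "AF1", "FC3", "F5")
  keep <- seq_len(3 + nOther)
  ch <- data.frame(
    source = src[keep], detector = det[keep],
    label = paste(src[keep], det[keep], sep = "-"),
    separation_cm = 3.0,
    x = c(6, 9, 7.5, 10.5, 15, 7.5, 9, 4.5)[keep],
    y = c(6, 6, 4.5, 6, 6, 7.5, 4.5, 6)[keep],
    stringsAsFactors = FALSE)
  new("FnirsMontage", channels = ch, sources = unique(ch$source),
      detectors = unique(ch$detector),
      ldlpfcLabels = c("F3-F5", "F3-F1", "F3-FC3"))
}

# ChromophoreSeries straight from matrices
makeSeries <- function(hboM, hbrM = -hboM / 3, fs = 3.9, branch = "raw",
                       labels = paste0("ch", seq_len(nrow(hboM)))) {
  rownames(hboM) <- labels
  rownames(hbrM) <- labels
  new("ChromophoreSeries", hbo = hboM, hbr = hbrM, fsHz = fs,
      channels = labels, branch = branch, filters = character(0))
}

# recording with given per-channel/wavelength intensity matrix list
makeRecording <- function(I760, I850, montage, fs = 3.9) {
  labels <- channelLabels(montage)
  stopifnot(nrow(I760) == length(labels))
  I <- array(0, c(nrow(I760), 2, ncol(I760)),
             dimnames = list(labels, c(760, 850), NULL))
  I[, 1, ] <- I760
  I[, 2, ] <- I850
  new("FnirsRecording", intensities = I, wavelengths = c(760, 850),
      fsHz = fs, montage = montage, qualityMask = rep(TRUE, length(labels)),
      groundTruth = list())
}

zeroCondAmps <- function(v = 0) {
  a <- setNames(rep(v, 4), conditionLevels())
  list(CN = list(LDLPFC = a, other = a), MCI = list(LDLPFC = a, other = a))
}

flatCoupling <- function(w) list(CN = c(LDLPFC = w, other = w),
                                 MCI = c(LDLPFC = w, other = w))

quietConfig <- function(...) {
  # a config with every nuisance and random subject effect switched off;
  # any argument can be overridden by the caller
  args <- list(noise = list(whiteSd = 0, ar = 0, cardiacAmp = 0, respAmp = 0,
                            mayerAmp = 0, driftAmp = 0),
               motion = list(spikePerMin = 0, spikeAmp = 0, shiftProb = 0,
                             shiftAmp = 0),
               fcCoupling = flatCoupling(0),
               subjectAmpSdLog = 0, subjectCouplingSdLogit = 0)
  usr <- list(...)
  args[names(usr)] <- usr
  do.call(simConfig, args)
}

cnSubject <- function(config = simConfig(nCn = 1, nMci = 1, seed = 1)) {
  simulateCohort(config)[1, ]
}
mciSubject <- function(config = simConfig(nCn = 1, nMci = 1, seed = 1)) {
  simulateCohort(config)[2, ]
}

# independent brute-force node metrics used as the graph oracle
bruteForceMetrics <- function(r, ldlpfc = character(0)) {
  N <- nrow(r)
  deg <- numeric(N); str <- numeric(N)
  for (i in seq_len(N)) for (j in seq_len(N)) if (i != j) {
    if (r[i, j] > 0) deg[i] <- deg[i] + 1
    str[i] <- str[i] + r[i, j]
  }
  maxw <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) maxw <- max(maxw, r[i, j])
  nd <- deg / (N - 1)
  ns <- if (maxw == 0) rep(0, N) else str / ((N - 1) * maxw)
  idx <- match(ldlpfc, rownames(r))
  idx <- idx[!is.na(idx)]
  list(dBar = mean(nd), wdBar = mean(ns),
       dLdp = if (length(idx)) mean(nd[idx]) else NA_real_,
       wdLdp = if (length(idx)) mean(ns[idx]) else NA_real_,
       degree = deg, strength = str)
}

# synthetic BetaTable for second-level tests: per-cell group means plus a
# subject intercept and residual noise
makeBetaTable <- function(nPerGroup = 20, channels = paste0("ch", 1:8),
                          effect = list(), tau = 1, sigma = 1,
                          conds = conditionLevels()) {
  ids <- sprintf("S%03d", seq_len(2 * nPerGroup))
  grp <- rep(c("CN", "MCI"), each = nPerGroup)
  rows <- expand.grid(subject_id = ids, channel = channels,
                      condition = conds, stringsAsFactors = FALSE)
  rows$group <- grp[match(rows$subject_id, ids)]
  u <- rnorm(length(ids), 0, tau)
  rows$beta <- u[match(rows$subject_id, ids)] + rnorm(nrow(rows), 0, sigma)
  for (nm in names(effect)) {
    # effect spec: list("ch1" = c(group, condition, delta))
    e <- effect[[nm]]
    sel <- rows$channel == nm & rows$group == e[[1]] & rows$condition == e[[2]]
    rows$beta[sel] <- rows$beta[sel] + as.numeric(e[[3]])
  }
  rows$chromophore <- "HbO"
  rows$se <- 1; rows$dof <- 100
  cohort <- data.frame(subject_id = ids, group = grp, stringsAsFactors = FALSE)
  list(betas = rows, cohort = cohort)
}
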