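# Synthetic cohorts with the statistical structure the analysis assumes:
# fNIRS sessions from a forward model that inverts the analysis chain,
# behavioral trial streams, EV event tables, and demographics — all with
# configurable planted group effects so every downstream stage is testable.

#' Simulation configuration
#'
#' Central configuration of the synthetic-cohort generator. Defaults encode
#' the study conditions: 20 + 20 subjects, reduced LDLPFC task amplitudes and
#' LDLPFC coupling in MCI, elevated CEEV fraction in MCI, impaired 2-back
#' performance in MCI, physiological noise at the cardiac (~1 Hz),
#' respiratory (~0.25 Hz) and Mayer-wave (~0.1 Hz) frequencies, and 100-400x
#' dilution EV acquisition at 1.5 uL/min for 120 s. Amplitudes are on the
#' micromolar scale of the chromophore series.
#'
#' @param nCn,nMci subject counts per group.
#' @param seed master RNG seed.
#' @param amplitude nested list group -> region ("LDLPFC"/"other") -> named
#'   condition amplitudes (uM).
#' @param noise list: whiteSd, ar (AR(1) coefficient), cardiacAmp, respAmp,
#'   mayerAmp, driftAmp.
#' @param motion list: spikePerMin, spikeAmp, shiftProb, shiftAmp.
#' @param fcCoupling nested list group -> c(LDLPFC =, other =) mixing weights
#'   in [0, 1): channels load on a shared latent field with weight w, so two
#'   channels with weights w1, w2 correlate at sqrt(w1 w2) times the spatial
#'   overlap of their latent profiles (exactly sqrt(w1 w2) when
#'   `fcSigmaCm = Inf`, i.e. a single global latent).
#' @param fcSigmaCm spatial length scale (cm) of the latent connectivity
#'   field; `Inf` collapses it to one global signal (default 12).
#' @param subjectAmpSdLog log-scale SD of the per-subject multiplicative
#'   amplitude factor (between-subject NVC variability).
#' @param subjectCouplingSdLogit logit-scale SD of per-subject coupling
#'   jitter.
#' @param behavior nested list group -> condition -> c(hit_p, fa_p, rt_mean,
#'   rt_sd) (ms).
#' @param ev list: ceevFraction per group, subject-level logit SD, class
#'   fractions, event count per aliquot, diameter distribution, dilution,
#'   aliquot count, fluorescence separation (log10 units).
#' @param fazekasCeevRho probit loading tying the simulated Fazekas grade to
#'   the subject's latent CEEV propensity.
#' @param restS,leadInS inter-block and lead-in rest (s).
#' @return list of class `SimConfig`.
#' @export
simConfig <- function(nCn = 20, nMci = 20, seed = 1,
                      amplitude = NULL, noise = NULL, motion = NULL,
                      fcCoupling = NULL, behavior = NULL, ev = NULL,
                      fazekasCeevRho = 1.3, restS = 20, leadInS = 20,
                      fcSigmaCm = 12, subjectAmpSdLog = 0.2,
                      subjectCouplingSdLogit = 0.15) {
  # concentration scales are physiological (uM): ~1-2 uM task responses over
  # ~0.8 uM noise keep delta-OD in the small-signal regime of 10^(-OD)
  amp0 <- list(
    CN = list(LDLPFC = c("0b_1" = 0.8, "0b_2" = 0.8, "1b" = 2.0, "2b" = 2.4),
              other = c("0b_1" = 0.5, "0b_2" = 0.5, "1b" = 0.6, "2b" = 0.6)),
    MCI = list(LDLPFC = c("0b_1" = 0.6, "0b_2" = 0.6, "1b" = 0.7, "2b" = 0.7),
               other = c("0b_1" = 0.5, "0b_2" = 0.5, "1b" = 0.55, "2b" = 0.55)))
  # ar = 0.95 concentrates noise power at low frequencies (1/f-like), the
  # regime where physiological fNIRS noise actually lives
  noise0 <- list(whiteSd = 0.8, ar = 0.95, cardiacAmp = 0.4, respAmp = 0.1,
                 mayerAmp = 0.1, driftAmp = 0.2)
  motion0 <- list(spikePerMin = 0.3, spikeAmp = 2.5, shiftProb = 0.1,
                  shiftAmp = 0.8)
  # coupling keeps LDLPFC edges significant in both groups (binary degree
  # saturates) while their strength drops in MCI, mirroring the reported
  # pattern: weighted LDLPFC degree reduced, global metrics preserved
  fc0 <- list(CN = c(LDLPFC = 0.8, other = 0.55),
              MCI = c(LDLPFC = 0.55, other = 0.55))
  beh0 <- list(
    CN = list("0b_1" = c(hit_p = 0.95, fa_p = 0.02, rt_mean = 480, rt_sd = 90),
              "0b_2" = c(hit_p = 0.95, fa_p = 0.02, rt_mean = 480, rt_sd = 90),
              "1b" = c(hit_p = 0.92, fa_p = 0.03, rt_mean = 550, rt_sd = 100),
              "2b" = c(hit_p = 0.85, fa_p = 0.05, rt_mean = 650, rt_sd = 120)),
    MCI = list("0b_1" = c(hit_p = 0.93, fa_p = 0.03, rt_mean = 500, rt_sd = 100),
               "0b_2" = c(hit_p = 0.93, fa_p = 0.03, rt_mean = 500, rt_sd = 100),
               "1b" = c(hit_p = 0.85, fa_p = 0.06, rt_mean = 600, rt_sd = 110),
               "2b" = c(hit_p = 0.65, fa_p = 0.12, rt_mean = 780, rt_sd = 140)))
  ev0 <- list(ceevFraction = c(CN = 0.055, MCI = 0.125), subjectSdLogit = 0.25,
              classFrac = c(debris = 0.30, platelet = 0.25, lymphocyte = 0.10,
                            endothelial = 0.20, mal_other = 0.15),
              nEvents = 50000, dilution = 200, nAliquots = 2,
              negMeanLog10 = 2, separationLog10 = 1.5, channelSdLog10 = 0.25,
              diamMeanLog = log(150), diamSdLog = 0.6,
              diamRange = c(80, 1300))
  merge2 <- function(def, usr) { if (is.null(usr)) return(def)
    def[names(usr)] <- usr; def }
  cfg <- list(nCn = nCn, nMci = nMci, seed = seed,
              amplitude = if (is.null(amplitude)) amp0 else amplitude,
              noise = merge2(noise0, noise), motion = merge2(motion0, motion),
              fcCoupling = if (is.null(fcCoupling)) fc0 else fcCoupling,
              behavior = if (is.null(behavior)) beh0 else behavior,
              ev = merge2(ev0, ev),
              fazekasCeevRho = fazekasCeevRho, restS = restS,
              leadInS = leadInS, fcSigmaCm = fcSigmaCm,
              subjectAmpSdLog = subjectAmpSdLog,
              subjectCouplingSdLogit = subjectCouplingSdLogit)
  stopifnot(cfg$nCn >= 1, cfg$nMci >= 1,
            all(unlist(lapply(cfg$fcCoupling, function(w) w >= 0 & w < 1))),
            cfg$ev$dilution >= 1)
  class(cfg) <- "SimConfig"
  cfg
}

.deriveSeed <- function(seed, offset) (as.integer(seed) + offset) %% 2147483647L

#' Simulate a cohort table
#'
#' Demographics and covariates with group-specific rates: ages ~ N(71, 7)
#' truncated at 50, comorbidity flags Bernoulli, a fluid-cognition composite,
#' and (for MCI) a Fazekas grade drawn from a binomial-probit of the
#' subject's latent CEEV propensity so that Fazekas and CEEV ratio are
#' positively associated.
#'
#' @param config a `SimConfig`.
#' @return data.frame (`CohortTable`): subject_id, group, age, sex,
#'   hypertension, depression_prior, fazekas, fluid_composite, plus the
#'   latent column ceev_latent used by [simulateEvSample()].
#' @export
simulateCohort <- function(config) {
  set.seed(.deriveSeed(config$seed, 101L))
  n <- config$nCn + config$nMci
  group <- c(rep("CN", config$nCn), rep("MCI", config$nMci))
  age <- 71 + 7 * rnorm(n)
  while (any(age < 50)) age[age < 50] <- 71 + 7 * rnorm(sum(age < 50))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  hyp <- rbinom(n, 1, ifelse(group == "CN", 0.30, 0.55)) == 1
  dep <- rbinom(n, 1, ifelse(group == "CN", 0.10, 0.30)) == 1
  fluid <- ifelse(group == "CN", 57 + 8 * rnorm(n), 38 + 12 * rnorm(n))
  z <- rnorm(n)                       # latent CEEV propensity
  rho <- config$fazekasCeevRho
  pBase <- qnorm(0.4) * sqrt(1 + rho^2)
  faz <- ifelse(group == "MCI",
                rbinom(n, 3, pnorm((pBase + rho * z) / 1)), NA_integer_)
  data.frame(subject_id = sprintf("S%02d", seq_len(n)), group = group,
             age = age, sex = sex, hypertension = hyp,
             depression_prior = dep, fazekas = as.integer(faz),
             fluid_composite = fluid, ceev_latent = z,
             stringsAsFactors = FALSE)
}

.ar1 <- function(n, phi, innovSd = 1) {
  if (phi == 0) return(rnorm(n, sd = innovSd))
  as.numeric(filter(rnorm(n, sd = innovSd), phi, method = "recursive"))
}

.standardize <- function(v) {
  s <- sd(v)
  if (s == 0) return(v * 0)
  (v - mean(v)) / s
}

#' Simulate one fNIRS session
#'
#' Forward model that the preprocessing + GLM chain inverts: ground-truth
#' HbO per channel is (per-condition boxcar convolved with the canonical
#' HRF) x group/region amplitude, plus a shared frontal signal realizing the
#' planted connectivity (mixing weight w per channel; pairwise correlation
#' sqrt(w_i w_j)), physiological sinusoids with per-channel random phase,
#' AR(1) noise, slow drift, and optional motion spikes/steps. HbR is
#' -HbO/3 plus independent noise. Chromophores are pushed through the
#' extinction-coefficient forward model to two-wavelength OD and intensities
#' I = 10^(-OD).
#'
#' @param subject one row of [simulateCohort()].
#' @param design a `TaskDesign`.
#' @param config a `SimConfig`.
#' @param montage montage (default [defaultMontage()]).
#' @param fs sampling rate (default 3.9 Hz).
#' @param seed per-session seed; `NULL` uses the ambient RNG state.
#' @return a [FnirsRecording-class]; `@groundTruth` holds the planted
#'   amplitude matrix and chromophore series.
#' @export
simulateFnirsSession <- function(subject, design, config,
                                 montage = defaultMontage(), fs = 3.9,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grp <- subject$group
  labels <- channelLabels(montage)
  nCh <- length(labels)
  nT <- ceiling(designDuration(design) * fs)
  X <- buildDesign(design, fs, nT)
  conds <- colnames(X)
  region <- ifelse(labels %in% ldlpfcChannels(montage), "LDLPFC", "other")
  ampM <- matrix(0, nCh, length(conds), dimnames = list(labels, conds))
  for (i in seq_len(nCh))
    ampM[i, ] <- config$amplitude[[grp]][[region[i]]][conds]
  subjFac <- exp(rnorm(1, 0, config$subjectAmpSdLog))
  ampM <- ampM * subjFac
  hboSig <- ampM %*% t(X)                           # nCh x nT

  nz <- config$noise
  w <- config$fcCoupling[[grp]][region]
  if (config$subjectCouplingSdLogit > 0 && any(w > 0)) {
    jit <- rnorm(2, 0, config$subjectCouplingSdLogit)
    names(jit) <- c("LDLPFC", "other")
    w <- ifelse(w > 0, stats::plogis(stats::qlogis(pmax(w, 1e-6)) + jit[region]), w)
  }
  # shared latent field: channels load on standardized latents whose weights
  # decay with scalp distance (length scale fcSigmaCm); pairwise noise
  # correlation = sqrt(w_i w_j) * spatial overlap
  sigma <- config$fcSigmaCm
  if (is.finite(sigma)) {
    pos <- as.matrix(montage@channels[, c("x", "y")])
    ctr <- as.matrix(expand.grid(x = c(1.5, 7.5, 13.5, 19.5), y = c(1.5, 7.5)))
    d2 <- outer(rowSums(pos^2), rowSums(ctr^2), `+`) - 2 * pos %*% t(ctr)
    G <- exp(-pmax(d2, 0) / (2 * sigma^2))
    G <- G / sqrt(rowSums(G^2))
    L <- t(vapply(seq_len(nrow(ctr)), function(k) .standardize(.ar1(nT, nz$ar)),
                  numeric(nT)))
    U <- G %*% L
  } else {
    U <- matrix(rep(.standardize(.ar1(nT, nz$ar)), each = nCh), nCh)
  }
  noiseM <- matrix(0, nCh, nT)
  for (i in seq_len(nCh)) {
    own <- .standardize(.ar1(nT, nz$ar))
    noiseM[i, ] <- (sqrt(w[i]) * U[i, ] + sqrt(1 - w[i]) * own) * nz$whiteSd
  }
  tt <- (seq_len(nT) - 1) / fs
  physM <- matrix(0, nCh, nT)
  for (spec in list(c(1.0, nz$cardiacAmp), c(0.25, nz$respAmp),
                    c(0.1, nz$mayerAmp))) {
    ph <- runif(nCh, 0, 2 * pi)
    physM <- physM + spec[2] * sin(outer(ph, 2 * pi * spec[1] * tt, `+`))
  }
  drift <- nz$driftAmp * outer(rnorm(nCh), tt / max(tt))

  hbo <- hboSig + noiseM + physM + drift
  # neural/vascular components mirror in HbR at -1/3; the pulsatile
  # (blood-volume) oscillations co-vary positively in both chromophores,
  # which is what the scalp-coupling screen keys on and CBSI removes
  hbr <- -(hboSig + noiseM + drift) / 3 + 0.3 * physM +
    0.05 * nz$whiteSd * matrix(rnorm(nCh * nT), nCh)

  mo <- config$motion
  nSpike <- rpois(1, mo$spikePerMin * nT / fs / 60 * nCh)
  if (nSpike > 0) for (k in seq_len(nSpike)) {
    i <- sample(nCh, 1); j <- sample(nT, 1)
    idx <- max(1, j - 1):min(nT, j + 1)
    a <- mo$spikeAmp * sample(c(-1, 1), 1) * c(0.5, 1, 0.5)[seq_along(idx)]
    hbo[i, idx] <- hbo[i, idx] + a       # common mode: same sign in both
    hbr[i, idx] <- hbr[i, idx] + a
  }
  if (runif(1) < mo$shiftProb) {
    i <- sample(nCh, 1); j <- sample(floor(nT / 2), 1) + floor(nT / 4)
    s <- mo$shiftAmp * sample(c(-1, 1), 1)
    hbo[i, j:nT] <- hbo[i, j:nT] + s
    hbr[i, j:nT] <- hbr[i, j:nT] + s
  }

  eps <- mbllExtinction()
  sep <- montage@channels$separation_cm
  dpf <- c(6, 6)
  I <- array(0, dim = c(nCh, 2, nT), dimnames = list(labels, rownames(eps), NULL))
  for (wv in 1:2) {
    od <- (eps[wv, "HbO"] * hbo + eps[wv, "HbR"] * hbr) *
      (sep * dpf[wv]) / 1000
    I[, wv, ] <- 10^(-od)
  }
  new("FnirsRecording", intensities = I, wavelengths = c(760, 850), fsHz = fs,
      montage = montage, qualityMask = rep(TRUE, nCh),
      groundTruth = list(amplitude = ampM, hbo = hbo, hbr = hbr,
                         coupling = w))
}

#' Simulate behavioral responses for a session
#'
#' Per trial: response ~ Bernoulli(hit_p) on targets and Bernoulli(fa_p) on
#' non-targets; reaction times of responses ~ Normal truncated at 150 ms.
#'
#' @param subject one row of [simulateCohort()].
#' @param design a `TaskDesign`.
#' @param config a `SimConfig`.
#' @param seed optional seed.
#' @return the design's trial table with added `responded` and `rt_ms`.
#' @export
simulateBehavior <- function(subject, design, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- design$trials
  par <- config$behavior[[subject$group]]
  pResp <- vapply(seq_len(nrow(tr)), function(i) {
    p <- par[[tr$condition[i]]]
    if (tr$is_target[i]) p[["hit_p"]] else p[["fa_p"]]
  }, numeric(1))
  tr$responded <- runif(nrow(tr)) < pResp
  rt <- vapply(seq_len(nrow(tr)), function(i) {
    p <- par[[tr$condition[i]]]
    max(150, rnorm(1, p[["rt_mean"]], p[["rt_sd"]]))
  }, numeric(1))
  tr$rt_ms <- ifelse(tr$responded, rt, NA_real_)
  tr
}

.rlnormTrunc <- function(n, meanlog, sdlog, range) {
  x <- rlnorm(n, meanlog, sdlog)
  while (any(bad <- x < range[1] | x > range[2]))
    x[bad] <- rlnorm(sum(bad), meanlog, sdlog)
  x
}

.evDrawClass <- function(n, cls, cfg) {
  pos <- function(on) cfg$negMeanLog10 + if (on) cfg$separationLog10 else 0
  mk <- function(endoOn, plOn, malOn)
    data.frame(endo_ch = 10^rnorm(n, pos(endoOn), cfg$channelSdLog10),
               lymph_platelet_ch = 10^rnorm(n, pos(plOn), cfg$channelSdLog10),
               mal_ch = 10^rnorm(n, pos(malOn), cfg$channelSdLog10))
  df <- switch(cls,
    debris = mk(FALSE, FALSE, FALSE),
    platelet = mk(FALSE, TRUE, FALSE),
    lymphocyte = mk(FALSE, TRUE, FALSE),
    eev = mk(TRUE, FALSE, FALSE),
    ceev = mk(TRUE, FALSE, TRUE),
    mal_other = mk(FALSE, FALSE, TRUE))
  df$diameter_nm <- .rlnormTrunc(n, cfg$diamMeanLog, cfg$diamSdLog,
                                 cfg$diamRange)
  df$true_label <- cls
  df
}

#' Simulate a stained EV sample with FMO controls
#'
#' Events are drawn from labeled subpopulations (debris, platelet,
#' lymphocyte, endothelial MAL-, endothelial MAL+ [CEEV], MAL+ other) with
#' log-normal fluorescence in each color channel and diameters from a
#' truncated log-normal spanning 80-1300 nm. The subject's CEEV fraction is
#' the group fraction modulated by the subject's latent propensity. FMO
#' control tables omit one stain at a time. Acquisition metadata (1.5
#' uL/min x 120 s, dilution) is attached; ground-truth labels are retained.
#'
#' @param subject one row of [simulateCohort()] (uses group and
#'   ceev_latent).
#' @param config a `SimConfig`.
#' @param nEvents events per table (default from config).
#' @param seed optional seed.
#' @return list: `stained` (event table), `fmo` (named list of three FMO
#'   tables), `acquisition`, `trueCeevFraction`.
#' @export
simulateEvSample <- function(subject, config, nEvents = config$ev$nEvents,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config$ev
  base <- cfg$ceevFraction[[subject$group]]
  z <- if ("ceev_latent" %in% names(subject)) subject$ceev_latent else 0
  f <- if (base <= 0) 0 else
    stats::plogis(stats::qlogis(base) + cfg$subjectSdLogit * z)
  frac <- cfg$classFrac / sum(cfg$classFrac)
  probs <- c(debris = unname(frac["debris"]),
             platelet = unname(frac["platelet"]),
             lymphocyte = unname(frac["lymphocyte"]),
             ceev = unname(frac["endothelial"]) * f,
             eev = unname(frac["endothelial"]) * (1 - f),
             mal_other = unname(frac["mal_other"]))
  draw <- function(n) {
    cnt <- as.vector(stats::rmultinom(1, n, probs))
    tab <- do.call(rbind, lapply(seq_along(probs)[cnt > 0], function(k)
      .evDrawClass(cnt[k], names(probs)[k], cfg)))
    tab[sample(nrow(tab)), , drop = FALSE]
  }
  stained <- draw(nEvents)
  fmo <- lapply(setNames(.evChannels(), .evChannels()), function(ch) {
    tab <- draw(nEvents)
    # omit the stain feeding this channel: redraw it from the negative pool
    tab[[ch]] <- 10^rnorm(nrow(tab), cfg$negMeanLog10, cfg$channelSdLog10)
    tab
  })
  acq <- evAcquisition(dilution_factor = cfg$dilution)
  attr(stained, "acquisition") <- acq
  list(stained = stained, fmo = fmo, acquisition = acq, trueCeevFraction = f)
}
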