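# End-to-end runner: simulate -> preprocess (both branches) -> NVC GLM ->
# connectivity -> behavior -> EV -> statistics -> classification.

.subjectFeatures <- function(subject, design, config, montage, fs = 3.9,
                             seedBase = 0L, nSurr = 200, motionCorrect = TRUE,
                             qualityScreen = TRUE, withEv = TRUE) {
  rec <- simulateFnirsSession(subject, design, config, montage, fs,
                              seed = .deriveSeed(config$seed, seedBase + 1L))
  qc <- if (qualityScreen) assessQuality(rec) else
    list(excluded = FALSE, poor = rep(FALSE, nrow(montage@channels)))
  if (qc$excluded)
    return(list(excluded = TRUE, reason = qc$reason, subject = subject))
  od <- intensitiesToOd(rec)
  # NVC branch
  odN <- if (motionCorrect) correctMotion(od, fs = fs) else od
  attr(odN, "fsHz") <- fs
  nvc <- dctHighpass(mbll(odN, montage, fs = fs))
  betas <- firstLevel(nvc, design, subjectId = subject$subject_id)
  # FC branch
  fc <- totalHemoglobin(cbsi(mbll(bandpassFc(od, fs = fs), montage, fs = fs)))
  set.seed(.deriveSeed(config$seed, seedBase + 2L))
  gm <- lapply(design$blocks$condition, function(cc) {
    g <- surrogateThreshold(blockCorrelation(fc, design, cc),
                            nSurr = nSurr)
    c(list(condition = cc), graphMetrics(g, montage))
  })
  gmdf <- do.call(rbind, lapply(gm, function(g)
    data.frame(condition = g$condition, dBar = g$dBar, wdBar = g$wdBar,
               dLdp = g$dLdp, wdLdp = g$wdLdp)))
  ta <- taskAverage(gmdf)
  # behavior
  beh <- blockPerformance(simulateBehavior(
    subject, design, config, seed = .deriveSeed(config$seed, seedBase + 3L)))
  beh$subject_id <- subject$subject_id
  # EV: nAliquots replicate aliquots, averaged
  ev <- NULL
  if (withEv) {
    evs <- lapply(seq_len(config$ev$nAliquots), function(a) {
      s <- simulateEvSample(subject, config,
                            seed = .deriveSeed(config$seed, seedBase + 10L + a))
      gates <- deriveGates(s$fmo)
      summarizeEvSample(gateEvents(s$stained, gates), s$acquisition)
    })
    ev <- if (length(evs) > 1) averageReplicates(evs) else evs[[1]]
  }
  list(excluded = FALSE, betas = betas, graphMetrics = gmdf,
       taskAveraged = ta, behavior = beh, ev = ev, subject = subject)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates a cohort under `config`, simulates and analyzes every subject
#' (NVC GLM, connectivity graphs, behavior, EV gating), then runs the
#' group-level layers: second-level load contrast, Mann-Whitney group
#' comparisons of the task-averaged metrics and CEEV measures, Spearman
#' CEEV-Fazekas association in MCI, and the LOOCV random-forest
#' classification protocol. Deterministic under a fixed config seed.
#'
#' @param config a `SimConfig` (see [simConfig()]).
#' @param design a `TaskDesign` (default [defaultTaskDesign()]).
#' @param montage montage (default [defaultMontage()]).
#' @param nSurr surrogate count for edge thresholding.
#' @param stages character subset of c("nvc", "fc", "behavior", "ev",
#'   "stats", "classify") to run after simulation; dependencies are
#'   enforced ("classify" needs "nvc", "fc" and "ev"; disabling "ev" runs
#'   classification on the reduced feature set with a warning).
#' @param classify list of classification options: k, nTrees, nRuns.
#' @return list with cohort, per-subject results, beta table, contrast maps,
#'   metric tables, test results and the model report.
#' @export
runPipeline <- function(config = simConfig(), design = defaultTaskDesign(),
                        montage = defaultMontage(), nSurr = 200,
                        stages = c("nvc", "fc", "behavior", "ev", "stats",
                                   "classify"),
                        classify = list(k = 3, nTrees = 500, nRuns = 100)) {
  cohort <- simulateCohort(config)
  subj <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort)))
    subj[[i]] <- .subjectFeatures(cohort[i, ], design, config, montage,
                                  seedBase = i * 100L, nSurr = nSurr,
                                  withEv = "ev" %in% stages)
  excluded <- vapply(subj, `[[`, TRUE, "excluded")
  kept <- subj[!excluded]
  if (!length(kept)) stop("pipeline stage 'preprocess': all subjects excluded")
  betas <- do.call(rbind, lapply(kept, `[[`, "betas"))
  fcTab <- do.call(rbind, lapply(kept, function(s)
    data.frame(subject_id = s$subject$subject_id,
               d_bar = s$taskAveraged[["dBar"]],
               wd_bar = s$taskAveraged[["wdBar"]],
               d_ldp = s$taskAveraged[["dLdp"]],
               wd_ldp = s$taskAveraged[["wdLdp"]])))
  behTab <- do.call(rbind, lapply(kept, `[[`, "behavior"))
  evTab <- if ("ev" %in% stages)
    do.call(rbind, lapply(kept, function(s)
      data.frame(subject_id = s$subject$subject_id,
                 ceev_ratio = s$ev$ceev_ratio_pct,
                 ceev_conc = s$ev$ceev_conc, eev_conc = s$ev$eev_conc)))
  else NULL
  out <- list(cohort = cohort, excluded = cohort$subject_id[excluded],
              betas = betas, fcMetrics = fcTab, behavior = behTab,
              ev = evTab, config = config)

  if ("nvc" %in% stages) {
    out$loadContrast <- cognitiveLoadContrast(betas, cohort, "difference")
    out$nvcLdlpfc <- ldlpfcAverage(betas, montage)
  }
  if ("stats" %in% stages) {
    grp <- function(tab, col) {
      m <- merge(tab, cohort[, c("subject_id", "group")], by = "subject_id")
      split(m[[col]], m$group)
    }
    st <- list()
    if (!is.null(out$nvcLdlpfc)) {
      g <- grp(out$nvcLdlpfc, "ldlpfc_beta")
      st$ldlpfc_nvc <- mannWhitney(g$CN, g$MCI)
    }
    for (col in c("d_bar", "wd_bar", "d_ldp", "wd_ldp")) {
      g <- grp(fcTab, col)
      st[[col]] <- mannWhitney(g$CN, g$MCI)
    }
    if (!is.null(evTab)) {
      g <- grp(evTab, "ceev_ratio")
      st$ceev_ratio <- mannWhitney(g$CN, g$MCI)
      m <- merge(evTab, cohort, by = "subject_id")
      m <- m[m$group == "MCI" & !is.na(m$fazekas), ]
      if (nrow(m) >= 3)
        st$ceev_fazekas <- spearmanCorr(m$ceev_ratio, m$fazekas)
    }
    d2 <- merge(behTab[behTab$condition == "2b", ],
                cohort[, c("subject_id", "group")], by = "subject_id")
    if (nrow(d2)) st$dprime_2b <- mannWhitney(d2$d_prime[d2$group == "CN"],
                                              d2$d_prime[d2$group == "MCI"])
    out$stats <- st
  }
  if ("classify" %in% stages) {
    if (!"ev" %in% stages)
      warning("EV stage disabled; classifying on the reduced feature set")
    feats <- assembleFeatures(out$nvcLdlpfc, fcTab, evTab, cohort)
    imp <- loocvImportance(feats, nTrees = classify$nTrees,
                           seed = .deriveSeed(config$seed, 7L))
    sel <- selectTopK(imp, k = classify$k)
    reps <- repeatedSplits(feats, sel, nRuns = classify$nRuns,
                           nTrees = classify$nTrees,
                           seed = .deriveSeed(config$seed, 8L))
    single <- evaluateSplit(feats, sel, nTrees = classify$nTrees,
                            seed = .deriveSeed(config$seed, 9L))
    out$model <- list(features = feats, importance = imp, selected = sel,
                      singleSplit = single, repeated = reps)
  }
  out
}
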