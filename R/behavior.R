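# Signal-detection scoring of n-back performance: hit/false-alarm rates with
# extreme-rate correction, d-prime, and reaction-time summaries.

#' Hit and false-alarm rates from a trial table
#'
#' Raw rates are hits/targets and false alarms/non-targets. Extreme rates
#' (exactly 0 or 1) are corrected by the 1/(2N) rule before any z-transform:
#' a rate of 1 becomes 1 - 1/(2N) and a rate of 0 becomes 1/(2N), with N the
#' relevant trial count. A log-linear alternative (add 0.5 to each count)
#' is available.
#'
#' @param trials data.frame with logical columns `is_target` and `responded`.
#' @param correction "halfN" (default) or "loglinear".
#' @return list: hit_rate, fa_rate (corrected), raw_hit_rate, raw_fa_rate,
#'   hits, false_alarms, n_targets, n_nontargets.
#' @export
behaviorRates <- function(trials, correction = c("halfN", "loglinear")) {
  correction <- match.arg(correction)
  stopifnot(all(c("is_target", "responded") %in% names(trials)))
  nT <- sum(trials$is_target)
  nN <- sum(!trials$is_target)
  if (nT == 0 || nN == 0)
    stop("need at least one target and one non-target trial")
  hits <- sum(trials$is_target & trials$responded)
  fa <- sum(!trials$is_target & trials$responded)
  if (correction == "loglinear") {
    hr <- (hits + 0.5) / (nT + 1)
    fr <- (fa + 0.5) / (nN + 1)
  } else {
    hr <- hits / nT
    fr <- fa / nN
    if (hr == 1) hr <- 1 - 1 / (2 * nT)
    if (hr == 0) hr <- 1 / (2 * nT)
    if (fr == 1) fr <- 1 - 1 / (2 * nN)
    if (fr == 0) fr <- 1 / (2 * nN)
  }
  list(hit_rate = hr, fa_rate = fr,
       raw_hit_rate = hits / nT, raw_fa_rate = fa / nN,
       hits = hits, false_alarms = fa, n_targets = nT, n_nontargets = nN)
}

#' Signal-detection accuracy d'
#'
#' d' = z(hit rate) - z(false-alarm rate), with z the standard-normal
#' quantile function. Rates must lie strictly inside (0, 1); apply the
#' extreme-rate correction of [behaviorRates()] upstream.
#'
#' @param hitRate,faRate rates in (0, 1).
#' @return numeric scalar d'.
#' @examples
#' dPrime(0.5, 0.5)            # 0
#' dPrime(0.84134, 0.15866)    # ~2
#' @export
dPrime <- function(hitRate, faRate) {
  if (any(c(hitRate, faRate) <= 0) || any(c(hitRate, faRate) >= 1))
    stop("rates must lie strictly in (0, 1); correct extreme rates upstream")
  qnorm(hitRate) - qnorm(faRate)
}

#' Mean reaction time of correct responses
#'
#' Arithmetic mean RT over hits (responded targets) only; correct rejections
#' carry no response and contribute no RT.
#'
#' @param trials data.frame with `is_target`, `responded` and `rt_ms`.
#' @return numeric scalar in ms, or `NA` (with attribute `flagged = TRUE`)
#'   when no correct response exists.
#' @export
meanRt <- function(trials) {
  hit <- trials$is_target & trials$responded
  if (!any(hit)) return(structure(NA_real_, flagged = TRUE))
  mean(trials$rt_ms[hit])
}

#' Per-condition performance summary
#'
#' Applies [behaviorRates()], [dPrime()] and [meanRt()] within each n-back
#' condition of a subject's trial table.
#'
#' @param trials trial table with columns condition, is_target, responded,
#'   rt_ms.
#' @param correction extreme-rate correction passed to [behaviorRates()].
#' @return data.frame (`BlockPerformance`): condition, n_targets,
#'   n_nontargets, hits, false_alarms, hit_rate, fa_rate, d_prime,
#'   mean_rt_correct_ms.
#' @export
blockPerformance <- function(trials, correction = "halfN") {
  conds <- intersect(conditionLevels(), unique(trials$condition))
  do.call(rbind, lapply(conds, function(cc) {
    tr <- trials[trials$condition == cc, ]
    r <- behaviorRates(tr, correction)
    data.frame(condition = cc, n_targets = r$n_targets,
               n_nontargets = r$n_nontargets, hits = r$hits,
               false_alarms = r$false_alarms, hit_rate = r$hit_rate,
               fa_rate = r$fa_rate, d_prime = dPrime(r$hit_rate, r$fa_rate),
               mean_rt_correct_ms = as.numeric(meanRt(tr)),
               stringsAsFactors = FALSE)
  }))
}
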