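# Task design and hemodynamic regressors, shared by the simulator and the
# GLM so the forward and inverse models cannot drift apart.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peaking near `peakS`, an
#' undershoot near `undershootS`, undershoot-to-peak ratio `ratio`), sampled
#' at times `t` (seconds) and scaled to unit peak so that GLM coefficients
#' are on the amplitude scale of the underlying chromophore change.
#'
#' @param t numeric vector of times in seconds (nonnegative).
#' @param peakS,undershootS,ratio shape parameters; defaults 6 s / 16 s / 1/6.
#' @return numeric vector, same length as `t`.
#' @export
canonicalHrf <- function(t, peakS = 6, undershootS = 16, ratio = 1 / 6) {
  stopifnot(all(t >= 0))
  h <- stats::dgamma(t, shape = peakS + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershootS + 1, rate = 1)
  h / max(h)
}

#' Construct an n-back task design
#'
#' Builds the block table and per-block trial stream for the working-memory
#' paradigm: blocks of 72 s each, one per condition, separated by rest.
#' Within each block, letters appear every `trialPeriodS` seconds and a fixed
#' fraction are targets (letter repeats per the n-back rule).
#'
#' @param order block order; a permutation of [conditionLevels()] (conditions
#'   may be omitted for reduced designs).
#' @param blockS block duration in seconds (72 by default).
#' @param restS inter-block rest in seconds.
#' @param leadInS initial rest before the first block.
#' @param trialPeriodS stimulus onset asynchrony within blocks.
#' @param targetFrac fraction of target trials per block.
#' @param seed optional seed controlling which trial positions are targets.
#' @return A list of class `TaskDesign` with elements `blocks`
#'   (data.frame: condition, onset_s, duration_s) and `trials`
#'   (data.frame: condition, onset_s, letter, is_target).
#' @export
taskDesign <- function(order = c("0b_1", "1b", "2b", "0b_2"),
                       blockS = 72, restS = 20, leadInS = 20,
                       trialPeriodS = 2.4, targetFrac = 0.25, seed = NULL) {
  stopifnot(all(order %in% conditionLevels()), !anyDuplicated(order))
  nb <- length(order)
  onsets <- leadInS + (seq_len(nb) - 1) * (blockS + restS)
  blocks <- data.frame(condition = order, onset_s = onsets,
                       duration_s = blockS, stringsAsFactors = FALSE)
  nTrials <- floor(blockS / trialPeriodS)
  nTarget <- max(1L, round(targetFrac * nTrials))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  trials <- do.call(rbind, lapply(seq_len(nb), function(b) {
    pos <- sort(sample(2:nTrials, nTarget))   # first trial can never repeat
    isT <- seq_len(nTrials) %in% pos
    letters_ <- sample(LETTERS[1:8], nTrials, replace = TRUE)
    for (k in which(isT)) letters_[k] <- letters_[max(1, k - 1)]
    data.frame(condition = order[b],
               onset_s = onsets[b] + (seq_len(nTrials) - 1) * trialPeriodS,
               letter = letters_, is_target = isT, stringsAsFactors = FALSE)
  }))
  structure(list(blocks = blocks, trials = trials), class = "TaskDesign")
}

#' Default task design of the study paradigm
#'
#' Four 72-s blocks in the order 0b_1, 1b, 2b, 0b_2 with 20-s rests.
#' @param seed seed for target placement.
#' @return A `TaskDesign`.
#' @export
defaultTaskDesign <- function(seed = 20L) taskDesign(seed = seed)

#' Total recording duration implied by a design (seconds)
#' @param design a `TaskDesign`.
#' @param leadOutS trailing rest after the last block.
#' @return numeric scalar, seconds.
#' @export
designDuration <- function(design, leadOutS = 20) {
  b <- design$blocks
  max(b$onset_s + b$duration_s) + leadOutS
}

#' Build the GLM design matrix for an n-back session
#'
#' One regressor per condition present in the design: the 72-s block boxcar
#' convolved with the canonical hemodynamic response function, sampled at
#' `fs`. Columns are labeled by condition.
#'
#' @param design a `TaskDesign`.
#' @param fs sampling rate in Hz.
#' @param nTime number of samples of the recording.
#' @param hrf hemodynamic response kernel: a function of time in seconds, or
#'   `NULL` for an impulse (regressor equals the boxcar).
#' @param hrfDurationS length of the sampled kernel.
#' @return numeric matrix `nTime` x number of conditions.
#' @export
buildDesign <- function(design, fs, nTime, hrf = canonicalHrf,
                        hrfDurationS = 32) {
  b <- design$blocks[order(design$blocks$onset_s), ]
  if (nrow(b) > 1 &&
      any(b$onset_s[-1] < (b$onset_s + b$duration_s)[-nrow(b)]))
    stop("overlapping task blocks")
  if (max(b$onset_s + b$duration_s) > nTime / fs + 1 / fs)
    stop("task blocks extend beyond the recording")
  conds <- intersect(conditionLevels(), unique(b$condition))
  # kernel normalized to unit sum so a sustained block plateaus at 1 and the
  # GLM coefficient is the block-response amplitude in the series' units
  kern <- if (is.null(hrf)) 1 else {
    k <- hrf((0:floor(hrfDurationS * fs)) / fs)
    k / sum(k)
  }
  X <- matrix(0, nTime, length(conds), dimnames = list(NULL, conds))
  tt <- (seq_len(nTime) - 1) / fs
  for (j in seq_along(conds)) {
    box <- numeric(nTime)
    for (i in which(b$condition == conds[j]))
      box[tt >= b$onset_s[i] & tt < b$onset_s[i] + b$duration_s[i]] <- 1
    v <- stats::convolve(box, rev(kern), type = "open")[seq_len(nTime)]
    X[, j] <- v
  }
  X
}
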