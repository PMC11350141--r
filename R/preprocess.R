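# Preprocessing: raw intensities -> analysis-ready chromophore series.
#
# Two branches share OD conversion and the MBLL:
#   NVC branch: quality screen -> OD -> motion handling -> MBLL -> DCT
#               high-pass (0.009 Hz); prewhitening happens jointly with the
#               GLM design inside firstLevel().
#   FC branch:  OD -> 5th-order zero-phase Butterworth band-pass
#               (0.0045-0.4 Hz) -> MBLL -> CBSI -> HbT.

#' Molar extinction coefficients at 760 and 850 nm
#'
#' Bundled extinction coefficients for oxy- and deoxyhemoglobin at the two
#' acquisition wavelengths, from the standard Gratzer/Kollias compilation,
#' in cm^-1 per millimolar. Both the forward simulator and the MBLL solver
#' use this table, so chromophore recovery is exact by construction.
#'
#' @return 2 x 2 numeric matrix; rows "760"/"850", columns "HbO"/"HbR".
#' @export
mbllExtinction <- function() {
  matrix(c(1.4866, 3.8437,
           2.5264, 1.7986),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("760", "850"), c("HbO", "HbR")))
}

#' Convert light intensities to optical-density changes
#'
#' Per channel and wavelength, delta-OD = -log10(I / mean(I)).
#'
#' @param recording a [FnirsRecording-class] with strictly positive
#'   intensities.
#' @return numeric array channel x wavelength x time of OD changes, with the
#'   recording's sampling rate attached as attribute `fsHz` and channel
#'   labels as dimnames.
#' @export
intensitiesToOd <- function(recording) {
  stopifnot(is(recording, "FnirsRecording"))
  I <- recording@intensities
  if (any(I <= 0)) stop("intensities must be strictly positive")
  od <- I
  for (i in seq_len(dim(I)[1])) for (w in 1:2) {
    x <- I[i, w, ]
    od[i, w, ] <- -log10(x / mean(x))
  }
  attr(od, "fsHz") <- recording@fsHz
  od
}

.butterFilt <- function(x, n, W, type) {
  bf <- signal::butter(n, W, type = type)
  signal::filtfilt(bf, x)
}

#' Scalp-coupling quality screen
#'
#' The coupling score of a channel is the Pearson correlation between its two
#' wavelengths' cardiac-band filtered signals (0.5 Hz up to the smaller of
#' 2.5 Hz and 95% of Nyquist); a strong shared cardiac pulsation indicates
#' good optode-scalp contact. A channel is poor if its score falls below
#' `threshold`. The subject is excluded if more than 80% of montage channels
#' are poor or if any LDLPFC channel is poor.
#'
#' @param recording a [FnirsRecording-class] with at least 30 s of data.
#' @param threshold poor-contact cutoff on the coupling score (default 0.75).
#' @return list with `score` (per channel), `poor` (logical), `excluded`
#'   (logical) and `reason` (character).
#' @export
assessQuality <- function(recording, threshold = 0.75) {
  stopifnot(is(recording, "FnirsRecording"))
  d <- dim(recording@intensities)
  fs <- recording@fsHz
  if (d[3] / fs < 30) stop("recording too short for quality assessment (< 30 s)")
  ny <- fs / 2
  hi <- min(2.5, 0.95 * ny)
  if (hi <= 0.5) stop("sampling rate too low to resolve the cardiac band")
  W <- c(0.5, hi) / ny
  labels <- channelLabels(recording)
  score <- vapply(seq_len(d[1]), function(i) {
    a <- .butterFilt(as.numeric(recording@intensities[i, 1, ]), 3, W, "pass")
    b <- .butterFilt(as.numeric(recording@intensities[i, 2, ]), 3, W, "pass")
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(a, b)
  }, numeric(1))
  names(score) <- labels
  poor <- score < threshold
  ldl <- ldlpfcChannels(recording@montage)
  reason <- character(0)
  if (mean(poor) > 0.8)
    reason <- c(reason, "more than 80% of prefrontal channels with poor contact")
  if (any(poor[ldl]))
    reason <- c(reason, sprintf("poor contact on LDLPFC channel(s): %s",
                                paste(ldl[poor[ldl]], collapse = ", ")))
  list(score = score, poor = poor, excluded = length(reason) > 0,
       reason = reason)
}

.despikeVector <- function(x, zThr, window) {
  n <- length(x)
  med <- stats::median(x)
  s <- stats::mad(x)
  if (s == 0) return(list(x = x, mask = rep(FALSE, n)))
  # spikes: robust z on the high-pass residual (local window median removed)
  half <- max(2L, floor(window / 2))
  loc <- stats::runmed(x, 2 * half + 1, endrule = "median")
  r <- x - loc
  sr <- stats::mad(r)
  if (sr == 0) return(list(x = x, mask = rep(FALSE, n)))
  mask <- abs(r) / sr > zThr
  if (any(mask)) {
    # widen support by one sample each side, interpolate over it
    idx <- which(mask)
    idx <- unique(pmin(pmax(c(idx - 1, idx, idx + 1), 1L), n))
    mask <- seq_len(n) %in% idx
    good <- which(!mask)
    if (length(good) >= 4)
      x[mask] <- stats::spline(good, x[good], xout = which(mask))$y
  }
  list(x = x, mask = mask)
}

.relevelSteps <- function(x, mask, stepThr) {
  # re-level baseline shifts: a jump in the despiked series larger than
  # stepThr robust SDs of the first difference is a candidate; it is applied
  # only when the estimated offset itself clears 3 robust SDs, so clean data
  # pass through untouched
  n <- length(x)
  s <- stats::mad(diff(x))
  if (s == 0) return(x)
  jumps <- which(abs(diff(x)) > stepThr * s)
  jumps <- jumps[!mask[jumps] & !mask[pmin(jumps + 1, n)]]
  if (!length(jumps)) return(x)
  sx <- stats::mad(x - stats::runmed(x, 21, endrule = "median"))
  for (j in jumps) {
    if (j < 5 || j > n - 5) next
    a <- max(1, j - 49):j
    b <- (j + 1):min(n, j + 50)
    off <- mean(x[b]) - mean(x[a])
    if (abs(off) > 3 * max(sx, 1e-12)) x[(j + 1):n] <- x[(j + 1):n] - off
  }
  x
}

#' Spike and baseline-shift motion correction
#'
#' Detects motion spikes as samples whose local-detrended robust z exceeds
#' `zThr` within a sliding window, replaces the spike support by cubic-spline
#' interpolation, and re-levels abrupt baseline steps. Operates on optical
#' densities (or any channel x time matrix / channel x wavelength x time
#' array); artifact-free input is returned unchanged.
#'
#' @param x numeric matrix (channels x time) or 3-d array
#'   (channel x wavelength x time).
#' @param zThr spike threshold in robust SD units (default 5).
#' @param windowS sliding-window length in seconds used for local detrending.
#' @param fs sampling rate; taken from `attr(x, "fsHz")` when absent.
#' @param stepThr baseline-step threshold in robust SDs of the first
#'   difference (default 4); set `Inf` to disable re-leveling.
#' @return object of the same shape with attribute `artifactMask` (logical,
#'   same shape) marking corrected samples.
#' @export
correctMotion <- function(x, zThr = 5, windowS = 10, fs = attr(x, "fsHz"),
                          stepThr = 4) {
  if (is.null(fs)) fs <- 3.9
  window <- max(5L, round(windowS * fs))
  if (is.matrix(x)) {
    mask <- x * 0 > 0
    for (i in seq_len(nrow(x))) {
      r <- .despikeVector(x[i, ], zThr, window)
      v <- .relevelSteps(r$x, r$mask, stepThr)
      x[i, ] <- v; mask[i, ] <- r$mask
    }
    attr(x, "artifactMask") <- mask
    return(x)
  }
  stopifnot(length(dim(x)) == 3)
  mask <- array(FALSE, dim(x))
  for (i in seq_len(dim(x)[1])) for (w in seq_len(dim(x)[2])) {
    r <- .despikeVector(x[i, w, ], zThr, window)
    x[i, w, ] <- .relevelSteps(r$x, r$mask, stepThr)
    mask[i, w, ] <- r$mask
  }
  attr(x, "artifactMask") <- mask
  x
}

#' Modified Beer-Lambert law
#'
#' Converts optical-density changes at the two wavelengths into relative
#' chromophore concentration changes by solving, per channel and sample, the
#' 2 x 2 system delta-OD(lambda) = (eps_HbO(lambda) dHbO + eps_HbR(lambda)
#' dHbR) * d * DPF(lambda), with source-detector distance d from the montage
#' and the differential pathlength factor DPF. Concentrations are returned on
#' the micromolar scale.
#'
#' @param od channel x wavelength x time OD array (see [intensitiesToOd()]).
#' @param montage the montage supplying per-channel separations.
#' @param dpf differential pathlength factor per wavelength (default 6 at
#'   both).
#' @param extinction 2 x 2 extinction matrix in cm^-1/mM
#'   (default [mbllExtinction()]).
#' @param fs sampling rate; taken from `attr(od, "fsHz")` when absent.
#' @return A [ChromophoreSeries-class] (branch "raw").
#' @export
mbll <- function(od, montage, dpf = c(6, 6), extinction = mbllExtinction(),
                 fs = attr(od, "fsHz")) {
  stopifnot(length(dim(od)) == 3, dim(od)[2] == 2)
  if (is.null(fs)) fs <- 3.9
  if (abs(det(extinction)) < 1e-12)
    stop("extinction matrix is singular; cannot separate HbO and HbR")
  labels <- channelLabels(montage)
  stopifnot(dim(od)[1] == length(labels))
  sep <- montage@channels$separation_cm
  nT <- dim(od)[3]
  hboM <- matrix(0, length(labels), nT, dimnames = list(labels, NULL))
  hbrM <- hboM
  for (i in seq_along(labels)) {
    A <- extinction * (dpf * sep[i]) / 1000  # /1000: mM -> uM concentration scale
    sol <- solve(A, rbind(od[i, 1, ], od[i, 2, ]))
    hboM[i, ] <- sol[1, ]
    hbrM[i, ] <- sol[2, ]
  }
  new("ChromophoreSeries", hbo = hboM, hbr = hbrM, fsHz = fs,
      channels = labels, branch = "raw", filters = character(0))
}

.dctBasis <- function(n, k) {
  # DCT-II vectors 0..k (constant included), orthonormalized
  B <- vapply(0:k, function(j) cos(pi * (seq_len(n) - 0.5) * j / n), numeric(n))
  sweep(B, 2, sqrt(colSums(B^2)), "/")
}

.dctProject <- function(M, fs, cutoff) {
  # remove DCT components with frequency below cutoff; M is time x series
  n <- nrow(M)
  if (cutoff >= fs / 2) stop("DCT cutoff must be below Nyquist")
  k <- ceiling(2 * n * cutoff / fs) - 1
  k <- max(k, 0)
  B <- .dctBasis(n, k)
  M - B %*% crossprod(B, M)
}

#' DCT-based high-pass filter
#'
#' Projects out the discrete-cosine basis vectors (including the constant)
#' whose frequency k*fs/(2N) lies below `cutoffHz`, removing slow drifts from
#' the NVC branch. The same projection is applied to the GLM design inside
#' [firstLevel()] so estimates stay unbiased.
#'
#' @param series a [ChromophoreSeries-class].
#' @param cutoffHz high-pass cutoff (default 0.009 Hz).
#' @return the filtered series, branch marked "nvc" and the filter logged.
#' @export
dctHighpass <- function(series, cutoffHz = 0.009) {
  stopifnot(is(series, "ChromophoreSeries"))
  if (series@branch == "fc")
    stop("DCT high-pass belongs to the NVC branch; series already on the FC branch")
  series@hbo <- t(.dctProject(t(series@hbo), series@fsHz, cutoffHz))
  series@hbr <- t(.dctProject(t(series@hbr), series@fsHz, cutoffHz))
  series@branch <- "nvc"
  series@filters <- c(series@filters, sprintf("dct:%g", cutoffHz))
  series
}

.fitAr <- function(resid, orderMax) {
  if (var(resid) < 1e-18) return(numeric(0))
  fit <- tryCatch(stats::ar(resid, aic = TRUE, order.max = orderMax,
                            method = "yule-walker", demean = TRUE),
                  error = function(e) NULL)
  if (is.null(fit) || fit$order == 0) return(numeric(0))
  phi <- fit$ar
  # Yule-Walker estimates are stationary by construction; guard anyway and
  # fall back to AR(1) if roots touch the unit circle
  if (any(Mod(polyroot(c(1, -phi))) <= 1 + 1e-8)) {
    warning("nonstationary AR fit; falling back to AR(1)")
    a <- stats::acf(resid, lag.max = 1, plot = FALSE)$acf[2]
    phi <- min(max(a, -0.98), 0.98)
  }
  phi
}

.arFilter <- function(v, phi) {
  # apply (1 - phi_1 B - ... - phi_p B^p) with zero pre-sample history
  if (!length(phi)) return(v)
  out <- v
  for (j in seq_along(phi)) {
    lag <- c(rep(0, j), v[seq_len(length(v) - j)])
    out <- out - phi[j] * lag
  }
  out
}

#' AR prewhitening of a series/design pair
#'
#' Fits an AR(p) model (p chosen by AIC up to `orderMax`) to the OLS
#' residuals of `y` on `X`, then applies the fitted AR filter to both the
#' series and the design so that downstream OLS inference is approximately
#' white. Zero-variance residuals (noiseless data) leave the pair untouched.
#'
#' @param y numeric vector (one channel's chromophore series).
#' @param X design matrix (time x regressors).
#' @param orderMax maximum AR order (default 4).
#' @return list with `y`, `X` (whitened) and `phi` (AR coefficients, possibly
#'   empty).
#' @export
prewhiten <- function(y, X, orderMax = 4) {
  stopifnot(length(y) == nrow(X))
  beta <- lm.fit(cbind(1, X), y)
  phi <- .fitAr(beta$residuals, orderMax)
  list(y = .arFilter(y, phi),
       X = apply(X, 2, .arFilter, phi = phi),
       phi = phi)
}

#' Zero-phase Butterworth band-pass for the FC branch
#'
#' Fifth-order Butterworth band-pass (0.0045-0.4 Hz by default), applied
#' forward and backward (zero phase) as a high-pass/low-pass cascade so the
#' timing of task blocks is not distorted. Accepts the OD array (filtering
#' each channel/wavelength) or a [ChromophoreSeries-class].
#'
#' @param x OD array (channel x wavelength x time) or ChromophoreSeries.
#' @param low,high band edges in Hz.
#' @param order filter order (default 5).
#' @param fs sampling rate; taken from attributes when absent.
#' @return filtered object of the same class, FC branch flagged.
#' @export
bandpassFc <- function(x, low = 0.0045, high = 0.4, order = 5,
                       fs = attr(x, "fsHz")) {
  filt1 <- function(v, fsv) {
    ny <- fsv / 2
    if (!(low > 0 && high > low && high < ny))
      stop("invalid band: need 0 < low < high < Nyquist")
    v <- v - mean(v)     # demeaning tames filtfilt edge transients at DC
    v <- .butterFilt(v, order, low / ny, "high")
    .butterFilt(v, order, high / ny, "low")
  }
  if (is(x, "ChromophoreSeries")) {
    if (x@branch == "nvc")
      stop("Butterworth band-pass belongs to the FC branch; series already on the NVC branch")
    x@hbo <- t(apply(x@hbo, 1, filt1, fsv = x@fsHz))
    x@hbr <- t(apply(x@hbr, 1, filt1, fsv = x@fsHz))
    x@branch <- "fc"
    x@filters <- c(x@filters, sprintf("butter%d:%g-%g", order, low, high))
    return(x)
  }
  stopifnot(length(dim(x)) == 3)
  if (is.null(fs)) fs <- 3.9
  for (i in seq_len(dim(x)[1])) for (w in seq_len(dim(x)[2]))
    x[i, w, ] <- filt1(x[i, w, ], fs)
  attr(x, "fsHz") <- fs
  attr(x, "fcFiltered") <- TRUE
  x
}

#' Correlation-based signal improvement (CBSI)
#'
#' Removes correlated HbO-HbR motion fluctuations per channel: with
#' alpha = SD(HbO)/SD(HbR), the corrected pair is
#' HbO' = (HbO - alpha HbR)/2 and HbR' = -HbO'/alpha, which makes the
#' corrected chromophores exactly anti-correlated. Channels with
#' zero-variance HbR are passed through and flagged.
#'
#' @param series a [ChromophoreSeries-class] (FC branch).
#' @return corrected series; attribute `cbsiSkipped` lists passthrough
#'   channels.
#' @export
cbsi <- function(series) {
  stopifnot(is(series, "ChromophoreSeries"))
  if (series@branch == "nvc")
    stop("CBSI belongs to the FC branch; series already on the NVC branch")
  skipped <- character(0)
  for (i in seq_len(nrow(series@hbo))) {
    so <- sd(series@hbo[i, ]); sr <- sd(series@hbr[i, ])
    if (sr == 0 || so == 0) { skipped <- c(skipped, series@channels[i]); next }
    alpha <- so / sr
    h <- (series@hbo[i, ] - alpha * series@hbr[i, ]) / 2
    series@hbo[i, ] <- h
    series@hbr[i, ] <- -h / alpha
  }
  series@filters <- c(series@filters, "cbsi")
  attr(series, "cbsiSkipped") <- skipped
  series
}

#' Total hemoglobin
#'
#' Adds HbT = HbO + HbR to the series.
#' @param series a [ChromophoreSeries-class].
#' @return the series with the `hbt` slot populated.
#' @export
totalHemoglobin <- function(series) {
  stopifnot(is(series, "ChromophoreSeries"))
  series@hbt <- series@hbo + series@hbr
  series@filters <- c(series@filters, "hbt")
  series
}
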