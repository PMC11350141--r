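#' @import methods
#' @import stats
NULL

#' Condition labels of the n-back paradigm
#'
#' The four block conditions used throughout the pipeline, in canonical
#' order: two 0-back baselines plus the 1-back and 2-back loads.
#' @return Character vector of length four.
#' @export
conditionLevels <- function() c("0b_1", "0b_2", "1b", "2b")

#' FnirsMontage: source-detector geometry of the frontal fNIRS cap
#'
#' Holds the channel table (source, detector, label, separation, nominal 2-D
#' scalp position), the optode label sets, and the ordered set of channels
#' covering the left dorsolateral prefrontal cortex (LDLPFC). Nominal
#' positions exist for plotting only; all analyses depend on channel labels
#' and the LDLPFC set.
#'
#' @slot channels data.frame with columns source, detector, label,
#'   separation_cm, x, y (one row per channel).
#' @slot sources character, source optode labels.
#' @slot detectors character, detector optode labels.
#' @slot ldlpfcLabels character, ordered LDLPFC channel labels.
#' @export
setClass("FnirsMontage",
  slots = c(
    channels = "data.frame",
    sources = "character",
    detectors = "character",
    ldlpfcLabels = "character"
  )
)

setValidity("FnirsMontage", function(object) {
  ch <- object@channels
  need <- c("source", "detector", "label", "separation_cm", "x", "y")
  if (!all(need %in% names(ch)))
    return(sprintf("channels must have columns: %s", paste(need, collapse = ", ")))
  if (anyDuplicated(ch$label)) return("channel labels must be unique")
  if (any(ch$separation_cm <= 0)) return("channel separations must be positive")
  if (!all(object@ldlpfcLabels %in% ch$label))
    return("ldlpfcLabels must be a subset of the channel labels")
  TRUE
})

#' FnirsRecording: dual-wavelength intensity time series
#'
#' Raw (or reconstructed) light-intensity time series for every
#' source-detector channel at the two near-infrared wavelengths, together
#' with the montage, sampling rate and a per-channel quality mask.
#'
#' @slot intensities numeric array channel x wavelength x time.
#' @slot wavelengths numeric(2), wavelengths in nm (760 and 850 by default).
#' @slot fsHz numeric(1), sampling rate in Hz.
#' @slot montage a [FnirsMontage-class].
#' @slot qualityMask logical per channel; TRUE = usable channel.
#' @slot groundTruth list; populated by the simulator with the planted
#'   chromophore series and amplitudes (empty for real data).
#' @export
setClass("FnirsRecording",
  slots = c(
    intensities = "array",
    wavelengths = "numeric",
    fsHz = "numeric",
    montage = "FnirsMontage",
    qualityMask = "logical",
    groundTruth = "list"
  )
)

setValidity("FnirsRecording", function(object) {
  d <- dim(object@intensities)
  if (length(d) != 3) return("intensities must be a channel x wavelength x time array")
  if (length(object@wavelengths) != 2 ||
      object@wavelengths[1] == object@wavelengths[2])
    return("exactly two distinct wavelengths are required")
  if (d[2] != 2) return("intensities must have two wavelength planes")
  if (d[1] != nrow(object@montage@channels))
    return("channel dimension must match the montage")
  if (length(object@fsHz) != 1 || object@fsHz <= 0) return("fsHz must be a positive scalar")
  if (length(object@qualityMask) != d[1])
    return("qualityMask must have one flag per channel")
  TRUE
})

#' ChromophoreSeries: HbO/HbR (and optionally HbT) concentration changes
#'
#' Relative chromophore concentration changes (micromolar scale) per channel,
#' produced by the modified Beer-Lambert law, with provenance flags recording
#' which preprocessing branch and filters produced the series. The
#' neurovascular-coupling (NVC) branch applies the DCT high-pass; the
#' functional-connectivity (FC) branch applies the Butterworth band-pass and
#' correlation-based signal improvement (CBSI).
#'
#' @slot hbo,hbr numeric matrices channel x time.
#' @slot hbt numeric matrix channel x time (0 x 0 until
#'   [totalHemoglobin()] is applied).
#' @slot fsHz sampling rate in Hz.
#' @slot channels character channel labels.
#' @slot branch "nvc", "fc", or "raw".
#' @slot filters character log of applied filters, e.g. "dct:0.009".
#' @export
setClass("ChromophoreSeries",
  slots = c(
    hbo = "matrix", hbr = "matrix", hbt = "matrix",
    fsHz = "numeric", channels = "character",
    branch = "character", filters = "character"
  ),
  prototype = prototype(hbt = matrix(numeric(0), 0, 0), branch = "raw",
                        filters = character(0))
)

setValidity("ChromophoreSeries", function(object) {
  if (!identical(dim(object@hbo), dim(object@hbr)))
    return("hbo and hbr must share dimensions")
  if (nrow(object@hbo) != length(object@channels))
    return("channel labels must match the row count")
  if (length(object@hbt) > 0) {
    if (!identical(dim(object@hbt), dim(object@hbo)))
      return("hbt must share dimensions with hbo/hbr")
    if (max(abs(object@hbt - (object@hbo + object@hbr))) > 1e-8)
      return("hbt must equal hbo + hbr elementwise")
  }
  TRUE
})

#' ConnectivityGraph: surrogate-thresholded block correlation network
#'
#' Symmetric matrix of thresholded Pearson coefficients r*_ij for one n-back
#' block: negative or non-significant correlations are zeroed, so entries lie
#' in [0, 1] with a zero diagonal. A Fisher z copy (atanh) is kept for
#' averaging across graphs.
#'
#' @slot condition block condition label.
#' @slot nodes retained channel labels.
#' @slot rStar thresholded correlation matrix.
#' @slot zMatrix atanh(rStar), capped just below atanh(1).
#' @export
setClass("ConnectivityGraph",
  slots = c(condition = "character", nodes = "character",
            rStar = "matrix", zMatrix = "matrix")
)

setValidity("ConnectivityGraph", function(object) {
  r <- object@rStar
  if (nrow(r) != ncol(r)) return("rStar must be square")
  if (nrow(r) != length(object@nodes)) return("nodes must match rStar dimension")
  if (max(abs(r - t(r))) > 1e-12) return("rStar must be symmetric")
  if (any(diag(r) != 0)) return("rStar diagonal must be zero")
  if (any(r < 0) || any(r > 1)) return("rStar entries must lie in [0, 1]")
  if (!identical(dim(object@zMatrix), dim(r)))
    return("zMatrix must share dimensions with rStar")
  TRUE
})

setMethod("show", "FnirsMontage", function(object) {
  cat(sprintf("FnirsMontage: %d channels (%d sources, %d detectors), %g cm separation\n",
              nrow(object@channels), length(object@sources),
              length(object@detectors), object@channels$separation_cm[1]))
  cat("  LDLPFC channels:", paste(object@ldlpfcLabels, collapse = ", "), "\n")
})

setMethod("show", "FnirsRecording", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("FnirsRecording: %d channels x %d wavelengths (%s nm) x %d samples @ %g Hz\n",
              d[1], d[2], paste(object@wavelengths, collapse = "/"), d[3], object@fsHz))
  cat(sprintf("  quality: %d/%d channels flagged good\n",
              sum(object@qualityMask), d[1]))
})

setMethod("show", "ChromophoreSeries", function(object) {
  cat(sprintf("ChromophoreSeries [%s branch]: %d channels x %d samples @ %g Hz\n",
              object@branch, nrow(object@hbo), ncol(object@hbo), object@fsHz))
  if (length(object@filters)) cat("  filters:", paste(object@filters, collapse = " -> "), "\n")
  if (length(object@hbt)) cat("  HbT present\n")
})

setMethod("show", "ConnectivityGraph", function(object) {
  cat(sprintf("ConnectivityGraph [%s]: %d nodes, %d retained edges\n",
              object@condition, length(object@nodes),
              sum(object@rStar[upper.tri(object@rStar)] > 0)))
})

# ---- accessors -------------------------------------------------------------

#' Accessors for the pipeline's S4 containers
#'
#' Small accessor family: `channelLabels()` returns channel labels,
#' `ldlpfcChannels()` the LDLPFC label set, `samplingRate()` the sampling
#' rate in Hz, `hbo()`/`hbr()`/`hbt()` the chromophore matrices, and
#' `rStar()` the thresholded correlation matrix of a graph.
#'
#' @param x an S4 object of this package.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setMethod("channelLabels", "FnirsMontage", function(x) x@channels$label)
#' @rdname accessors
#' @export
setMethod("channelLabels", "FnirsRecording", function(x) x@montage@channels$label)
#' @rdname accessors
#' @export
setMethod("channelLabels", "ChromophoreSeries", function(x) x@channels)
#' @rdname accessors
#' @export
setGeneric("ldlpfcChannels", function(x) standardGeneric("ldlpfcChannels"))
#' @rdname accessors
#' @export
setMethod("ldlpfcChannels", "FnirsMontage", function(x) x@ldlpfcLabels)
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "FnirsRecording", function(x) x@fsHz)
#' @rdname accessors
#' @export
setMethod("samplingRate", "ChromophoreSeries", function(x) x@fsHz)
#' @rdname accessors
#' @export
setGeneric("hbo", function(x) standardGeneric("hbo"))
#' @rdname accessors
#' @export
setMethod("hbo", "ChromophoreSeries", function(x) x@hbo)
#' @rdname accessors
#' @export
setGeneric("hbr", function(x) standardGeneric("hbr"))
#' @rdname accessors
#' @export
setMethod("hbr", "ChromophoreSeries", function(x) x@hbr)
#' @rdname accessors
#' @export
setGeneric("hbt", function(x) standardGeneric("hbt"))
#' @rdname accessors
#' @export
setMethod("hbt", "ChromophoreSeries", function(x) {
  if (!length(x@hbt)) stop("HbT not computed; call totalHemoglobin() first")
  x@hbt
})
#' @rdname accessors
#' @export
setGeneric("rStar", function(x) standardGeneric("rStar"))
#' @rdname accessors
#' @export
setMethod("rStar", "ConnectivityGraph", function(x) x@rStar)
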