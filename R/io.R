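# Delimited-text I/O for recordings and result tables.
#
# Recordings travel as wide CSV: UTF-8, comma-separated, "." decimal, header
# mandatory, time in seconds as the first column, then one column per
# channel/wavelength named "<channel>_<wavelength>" (e.g. "F3-F5_760").

#' Write an fNIRS recording to wide CSV
#'
#' @param recording a [FnirsRecording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readRecordingCsv()]
#' @export
writeRecordingCsv <- function(recording, path) {
  stopifnot(is(recording, "FnirsRecording"))
  d <- dim(recording@intensities)
  labels <- channelLabels(recording)
  tt <- (seq_len(d[3]) - 1) / recording@fsHz
  cols <- vector("list", d[1] * 2)
  nms <- character(d[1] * 2)
  k <- 0
  for (i in seq_len(d[1])) for (w in 1:2) {
    k <- k + 1
    cols[[k]] <- recording@intensities[i, w, ]
    nms[k] <- sprintf("%s_%d", labels[i], recording@wavelengths[w])
  }
  df <- data.frame(time_s = tt, setNames(cols, nms), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an fNIRS recording from wide CSV
#'
#' Channels of the supplied montage that are absent from the file are kept in
#' the returned object with constant unit intensity and flagged poor in the
#' quality mask; all channels present in the file must carry both
#' wavelengths.
#'
#' @param path CSV file written by [writeRecordingCsv()] (or equivalent).
#' @param montage montage to resolve channel labels against; defaults to
#'   [defaultMontage()].
#' @param fsHz sampling rate; if `NULL`, inferred from the time column.
#' @return A [FnirsRecording-class].
#' @export
readRecordingCsv <- function(path, montage = defaultMontage(), fsHz = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop("malformed recording CSV: missing required field 'time_s'")
  sig <- setdiff(names(df), "time_s")
  m <- regmatches(sig, regexec("^(.*)_(\\d+)$", sig))
  bad <- vapply(m, length, 1L) != 3
  if (any(bad))
    stop("malformed recording CSV: column(s) not of the form <channel>_<wavelength>: ",
         paste(sig[bad], collapse = ", "))
  chan <- vapply(m, `[`, "", 2)
  wl <- as.numeric(vapply(m, `[`, "", 3))
  wavelengths <- sort(unique(wl))
  if (length(wavelengths) != 2)
    stop("recording must declare exactly two wavelengths, found: ",
         paste(wavelengths, collapse = ", "))
  labels <- channelLabels(montage)
  nT <- nrow(df)
  if (is.null(fsHz)) {
    dt <- diff(df$time_s)
    if (nT < 2 || any(dt <= 0)) stop("malformed recording CSV: field 'time_s' not increasing")
    fsHz <- 1 / stats::median(dt)
  }
  intens <- array(1, dim = c(length(labels), 2, nT),
                  dimnames = list(labels, wavelengths, NULL))
  good <- rep(FALSE, length(labels))
  for (i in seq_along(labels)) {
    sel <- chan == labels[i]
    if (sum(sel) == 0) next
    if (!setequal(wl[sel], wavelengths))
      stop("channel ", labels[i], " present at only one wavelength")
    for (w in 1:2) intens[i, w, ] <- df[[sig[sel][wl[sel] == wavelengths[w]]]]
    good[i] <- TRUE
  }
  new("FnirsRecording", intensities = intens, wavelengths = wavelengths,
      fsHz = fsHz, montage = montage, qualityMask = good, groundTruth = list())
}

#' Write a homogeneous list of records (or a data.frame) as CSV
#'
#' Deterministic column order (order of the first record), header row, comma
#' separation.
#'
#' @param records a nonempty data.frame, or list of named lists/vectors with
#'   identical fields.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTable <- function(records, path) {
  if (is.data.frame(records)) {
    if (nrow(records) == 0) stop("records must be nonempty")
    df <- records
  } else {
    if (!is.list(records) || length(records) == 0) stop("records must be nonempty")
    fields <- names(records[[1]])
    if (is.null(fields) || any(fields == "")) stop("records must have named fields")
    ok <- vapply(records, function(r) identical(sort(names(r)), sort(fields)), TRUE)
    if (!all(ok)) stop("records must share an identical field set")
    df <- do.call(rbind, lapply(records, function(r)
      as.data.frame(as.list(r)[fields], stringsAsFactors = FALSE)))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
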