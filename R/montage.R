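# Default 48-channel frontal montage.
#
# The cap uses 16 sources and 16 detectors arranged on a 4 x 8 checkerboard
# over the frontal cortex (rows AF, F, FC, C of the 10-20/10-10 system),
# every channel a 3 cm source-detector pair. Only the three LDLPFC channels
# (F3-F5, F3-F1, F3-FC3) are anatomically binding; the remaining labels are a
# documented convention. Grid coordinates are nominal (cm) and used for
# plotting only.

.montageGrid <- function() {
  cols <- c("7", "5", "3", "1", "2", "4", "6", "8")
  rows <- list(
    AF = paste0("AF", cols),
    F  = paste0("F", cols),
    FC = c("FT7", paste0("FC", cols[2:7]), "FT8"),
    C  = c("T7", paste0("C", cols[2:7]), "T8")
  )
  grid <- expand.grid(r = 1:4, c = 1:8)
  grid$label <- mapply(function(r, c) rows[[r]][c], grid$r, grid$c)
  # checkerboard: odd (r + c) positions carry sources, even carry detectors
  grid$role <- ifelse((grid$r + grid$c) %% 2 == 1, "source", "detector")
  grid$x <- (grid$c - 1) * 3
  grid$y <- (4 - grid$r) * 3
  grid
}

#' Default 48-channel frontal fNIRS montage
#'
#' Returns the standard montage used throughout the pipeline: 16 sources and
#' 16 detectors over the frontal cortex, 48 source-detector channels all
#' separated by 3.0 cm, with the LDLPFC channel set \{F3-F5, F3-F1, F3-FC3\}.
#' Deterministic (no randomness); repeated calls return identical objects.
#'
#' @return A [FnirsMontage-class] object.
#' @examples
#' m <- defaultMontage()
#' nrow(m@channels)        # 48
#' ldlpfcChannels(m)
#' @export
defaultMontage <- function() {
  grid <- .montageGrid()
  key <- function(r, c) paste(r, c, sep = ",")
  pos <- setNames(seq_len(nrow(grid)), key(grid$r, grid$c))
  edges <- rbind(
    do.call(rbind, lapply(1:4, function(r)
      cbind(r1 = r, c1 = 1:7, r2 = r, c2 = 2:8))),
    do.call(rbind, lapply(1:3, function(r)
      cbind(r1 = r, c1 = 1:8, r2 = r + 1, c2 = 1:8)))
  )
  # trim four alternating edges of the lowest row to reach the cap's 48
  # channels while keeping every optode connected (16 sources, 16 detectors)
  drop <- c("4,1-4,2", "4,3-4,4", "4,5-4,6", "4,7-4,8")
  ek <- paste(key(edges[, "r1"], edges[, "c1"]), key(edges[, "r2"], edges[, "c2"]),
              sep = "-")
  edges <- edges[!ek %in% drop, , drop = FALSE]
  stopifnot(nrow(edges) == 48)

  a <- grid[pos[key(edges[, "r1"], edges[, "c1"])], ]
  b <- grid[pos[key(edges[, "r2"], edges[, "c2"])], ]
  src <- ifelse(a$role == "source", a$label, b$label)
  det <- ifelse(a$role == "source", b$label, a$label)
  channels <- data.frame(
    source = src, detector = det,
    label = paste(src, det, sep = "-"),
    separation_cm = 3.0,
    x = (a$x + b$x) / 2, y = (a$y + b$y) / 2,
    stringsAsFactors = FALSE
  )
  new("FnirsMontage",
      channels = channels,
      sources = sort(unique(src)),
      detectors = sort(unique(det)),
      ldlpfcLabels = c("F3-F5", "F3-F1", "F3-FC3"))
}
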