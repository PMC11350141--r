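# Graph-theoretic functional connectivity on total-hemoglobin block windows:
# Pearson correlation per 72-s block, circular-shift surrogate thresholding,
# and normalized binary/weighted node-degree metrics.

#' Raw Pearson correlation matrix for one task block
#'
#' Correlates the FC-branch HbT series of all retained channels over the
#' 72-s window of the requested block.
#'
#' @param series a [ChromophoreSeries-class] with HbT (FC branch).
#' @param design a `TaskDesign`.
#' @param block block condition label (e.g. "2b") or block row index.
#' @param channels optional subset of channel labels.
#' @return list with `r` (correlation matrix), `window` (sample indices) and
#'   `condition`.
#' @export
blockCorrelation <- function(series, design, block, channels = NULL) {
  H <- hbt(series)
  labels <- series@channels
  if (!is.null(channels)) {
    H <- H[match(channels, labels), , drop = FALSE]
    labels <- channels
  }
  b <- design$blocks
  row <- if (is.character(block)) match(block, b$condition) else as.integer(block)
  if (is.na(row) || row < 1 || row > nrow(b)) stop("no such block: ", block)
  fs <- series@fsHz
  i0 <- floor(b$onset_s[row] * fs) + 1
  i1 <- floor((b$onset_s[row] + b$duration_s[row]) * fs)
  if (i1 > ncol(H)) stop("block extends beyond the recording")
  W <- H[, i0:i1, drop = FALSE]
  r <- cor(t(W))
  dimnames(r) <- list(labels, labels)
  list(r = r, window = c(i0, i1), condition = b$condition[row],
       data = W)
}

.circularNull <- function(W) {
  # circular cross-correlation of every channel pair at every shift, via FFT;
  # row s+1 holds corr(x_i, x_j circularly shifted by s)
  n <- ncol(W)
  Z <- t(W) - matrix(colMeans(t(W)), n, nrow(W), byrow = TRUE)
  Z <- sweep(Z, 2, sqrt(colMeans(Z^2)), "/")           # population scaling
  F <- mvfft(Z)
  C <- ncol(Z)
  pairs <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  P <- F[, pairs[, 1], drop = FALSE] * Conj(F[, pairs[, 2], drop = FALSE])
  cc <- Re(mvfft(P, inverse = TRUE)) / n^2
  list(cc = cc, pairs = pairs)
}

#' Surrogate-based significance thresholding of a correlation matrix
#'
#' For each channel pair, a null distribution is built from `nSurr` random
#' circular time-shifts of one channel (shifts preserve each channel's
#' autocorrelation while destroying cross-correlation); the one-sided p-value
#' is the fraction of surrogate correlations at least as large as the
#' observed one. An edge is retained (r* = r) only if p < `alpha` and r > 0;
#' otherwise r* = 0. Alternatively, `scheme = "parametric"` thresholds by the
#' standard t-test on r.
#'
#' @param bc result of [blockCorrelation()] (or a list with `r`, `data`,
#'   `condition`).
#' @param alpha significance level (default 0.05).
#' @param nSurr number of surrogate shifts (default 200; at least 19 at
#'   alpha = 0.05 so p < alpha is resolvable).
#' @param scheme "circular" (default) or "parametric".
#' @return a [ConnectivityGraph-class].
#' @export
surrogateThreshold <- function(bc, alpha = 0.05, nSurr = 200,
                               scheme = c("circular", "parametric")) {
  scheme <- match.arg(scheme)
  r <- bc$r
  C <- nrow(r)
  keep <- matrix(FALSE, C, C)
  if (scheme == "circular") {
    if (nSurr < ceiling(1 / alpha) - 1)
      stop(sprintf("nSurr = %d cannot resolve p < %g; need at least %d surrogates",
                   nSurr, alpha, ceiling(1 / alpha) - 1))
    W <- bc$data
    n <- ncol(W)
    null <- .circularNull(W)
    shifts <- if (nSurr <= n - 1) sample(seq_len(n - 1), nSurr)
              else sample(seq_len(n - 1), nSurr, replace = TRUE)
    surr <- null$cc[shifts + 1, , drop = FALSE]
    obs <- null$cc[1, ]
    p <- colMeans(surr >= matrix(obs, nrow(surr), length(obs), byrow = TRUE))
    for (k in seq_len(nrow(null$pairs))) {
      i <- null$pairs[k, 1]; j <- null$pairs[k, 2]
      keep[i, j] <- keep[j, i] <- p[k] < alpha
    }
  } else {
    n <- ncol(bc$data)
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
    p <- pt(tt, df = n - 2, lower.tail = FALSE)   # one-sided, positive tail
    keep <- p < alpha
  }
  rStar <- ifelse(keep & r > 0, r, 0)
  diag(rStar) <- 0
  rStar <- pmin(rStar, 1)
  z <- atanh(pmin(rStar, 1 - 1e-12))
  dimnames(rStar) <- dimnames(r); dimnames(z) <- dimnames(r)
  new("ConnectivityGraph", condition = as.character(bc$condition),
      nodes = rownames(r), rStar = rStar, zMatrix = z)
}

#' Binary and weighted node-degree metrics of a connectivity graph
#'
#' Node degree D_i counts a node's retained edges; node strength wD_i sums
#' their weights. Normalized metrics lie in [0, 1]: binary node values are
#' D_i/(N-1) and the global mean is Dbar; weighted node values divide
#' strength by (N-1) times the maximum retained edge weight of the graph
#' (`weightedNorm = "maxweight"`, the default) or by (N-1) alone
#' (`"possible"`, since weights are <= 1). LDLPFC metrics average the three
#' LDLPFC channels' normalized node values.
#'
#' @param graph a [ConnectivityGraph-class] (or bare r* matrix with node
#'   dimnames).
#' @param montage montage supplying the LDLPFC label set.
#' @param weightedNorm normalization of weighted metrics (see above).
#' @return list with `perNode` (data.frame: node, degree, strength,
#'   normDegree, normStrength) and scalars `dBar`, `wdBar`, `dLdp`, `wdLdp`.
#' @export
graphMetrics <- function(graph, montage = defaultMontage(),
                         weightedNorm = c("maxweight", "possible")) {
  weightedNorm <- match.arg(weightedNorm)
  r <- if (is(graph, "ConnectivityGraph")) rStar(graph) else graph
  N <- nrow(r)
  if (N < 2) stop("graph needs at least 2 nodes")
  nodes <- rownames(r)
  if (is.null(nodes)) nodes <- paste0("ch", seq_len(N))
  deg <- rowSums(r > 0)
  strength <- rowSums(r)
  normDeg <- deg / (N - 1)
  maxw <- max(r)
  normStr <- if (maxw == 0) rep(0, N) else switch(weightedNorm,
    maxweight = strength / ((N - 1) * maxw),
    possible = strength / (N - 1))
  perNode <- data.frame(node = nodes, degree = deg, strength = strength,
                        normDegree = normDeg, normStrength = normStr,
                        stringsAsFactors = FALSE)
  ldl <- intersect(ldlpfcChannels(montage), nodes)
  ldlIdx <- match(ldl, nodes)
  list(perNode = perNode,
       dBar = mean(normDeg), wdBar = mean(normStr),
       dLdp = if (length(ldlIdx)) mean(normDeg[ldlIdx]) else NA_real_,
       wdLdp = if (length(ldlIdx)) mean(normStr[ldlIdx]) else NA_real_)
}

#' Task-averaged graph metrics
#'
#' Arithmetic mean over block conditions of each normalized scalar metric
#' ("available-mean": missing blocks are skipped).
#'
#' @param metricsByBlock list of [graphMetrics()] results (one per block) or
#'   a data.frame with one row per block and metric columns.
#' @return named numeric vector with dBar, wdBar, dLdp, wdLdp.
#' @export
taskAverage <- function(metricsByBlock) {
  if (is.data.frame(metricsByBlock)) {
    keep <- intersect(c("dBar", "wdBar", "dLdp", "wdLdp"),
                      names(metricsByBlock))
    return(colMeans(metricsByBlock[, keep, drop = FALSE], na.rm = TRUE))
  }
  stopifnot(length(metricsByBlock) >= 1)
  m <- vapply(metricsByBlock, function(g)
    c(dBar = g$dBar, wdBar = g$wdBar, dLdp = g$dLdp, wdLdp = g$wdLdp),
    numeric(4))
  rowMeans(m, na.rm = TRUE)
}

#' Fisher-z average of connectivity graphs
#'
#' Elementwise mean of atanh(r*) across graphs sharing a node set (subjects
#' and/or blocks), returned both on the z scale and back-transformed.
#'
#' @param graphs list of [ConnectivityGraph-class] objects.
#' @return list with matrices `z` (mean atanh) and `r` (tanh of the mean).
#' @export
fisherAverage <- function(graphs) {
  stopifnot(length(graphs) >= 1)
  nodes <- graphs[[1]]@nodes
  for (g in graphs)
    if (!identical(g@nodes, nodes)) stop("graphs must share an identical node set")
  z <- Reduce(`+`, lapply(graphs, function(g) g@zMatrix)) / length(graphs)
  list(z = z, r = tanh(z))
}
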