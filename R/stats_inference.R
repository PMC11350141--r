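# Statistics layer: Mann-Whitney, mixed two-way ANOVA with Bonferroni post
# hocs, ROUT outlier screening, Spearman and Fisher's exact tests, Cohen's d
# from summary statistics, and a BH-FDR utility.

#' Two-sided Mann-Whitney U test
#'
#' Exact p-value for small samples (both n <= 8, no ties), normal
#' approximation with tie correction otherwise. The reported statistic is U
#' for the first sample.
#'
#' @param x,y numeric samples (nonempty).
#' @return list (`TestResult`): statistic, p_value, n1, n2, method.
#' @export
mannWhitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  exact <- length(x) <= 8 && length(y) <= 8 &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n1 = length(x), n2 = length(y),
       method = if (exact) "Mann-Whitney (exact)" else
         "Mann-Whitney (normal approximation, tie corrected)")
}

#' Mixed two-way ANOVA with Bonferroni post hoc comparisons
#'
#' Group (between subjects) by task (within subjects) analysis of variance
#' with subject error strata; Bonferroni-adjusted unpaired group comparisons
#' within each task level (multiplier = number of task levels). Subjects
#' missing a task level are excluded listwise with a warning.
#'
#' @param data data.frame with columns subject, group, task, value.
#' @return list: `anova` (data.frame: effect, df1, df2, F, p), `posthoc`
#'   (data.frame: task, estimate, p_raw, p_adjusted), `n_excluded`.
#' @export
mixedAnovaBonferroni <- function(data) {
  stopifnot(all(c("subject", "group", "task", "value") %in% names(data)))
  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$task <- factor(data$task)
  if (nlevels(data$group) < 2 || nlevels(data$task) < 2)
    stop("need at least 2 group and 2 task levels")
  nTask <- nlevels(data$task)
  cnt <- table(data$subject)
  bad <- names(cnt)[cnt < nTask]
  if (length(bad)) {
    warning(length(bad), " subject(s) missing task levels; excluded listwise")
    data <- data[!data$subject %in% bad, ]
    data$subject <- droplevels(data$subject)
  }
  fit <- aov(value ~ group * task + Error(subject), data = data)
  sm <- summary(fit)
  btw <- as.data.frame(sm[["Error: subject"]][[1]])
  wth <- as.data.frame(sm[["Error: Within"]][[1]])
  pick <- function(tab, name) {
    i <- match(name, trimws(rownames(tab)))
    c(df1 = tab$Df[i], F = tab$`F value`[i], p = tab$`Pr(>F)`[i])
  }
  an <- rbind(group = c(pick(btw, "group"),
                        df2 = btw$Df[match("Residuals", trimws(rownames(btw)))]),
              task = c(pick(wth, "task"),
                       df2 = wth$Df[match("Residuals", trimws(rownames(wth)))]),
              `group:task` = c(pick(wth, "group:task"),
                               df2 = wth$Df[match("Residuals", trimws(rownames(wth)))]))
  anova <- data.frame(effect = rownames(an), df1 = an[, "df1"],
                      df2 = an[, "df2"], F = an[, "F"], p = an[, "p"],
                      row.names = NULL)
  g <- levels(data$group)
  posthoc <- do.call(rbind, lapply(levels(data$task), function(tk) {
    d <- data[data$task == tk, ]
    a <- d$value[d$group == g[1]]; b <- d$value[d$group == g[2]]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(task = tk, estimate = NA_real_, p_raw = NA_real_,
                        p_adjusted = NA_real_))
    tt <- t.test(a, b)
    data.frame(task = tk, estimate = mean(a) - mean(b),
               p_raw = tt$p.value, p_adjusted = min(1, tt$p.value * nTask))
  }))
  list(anova = anova, posthoc = posthoc, n_excluded = length(bad))
}

#' ROUT-style outlier screen for a group vector
#'
#' The robust-regression-and-outlier-removal idea applied to a plain sample
#' (the regression degenerates to a robust constant fit): residuals from the
#' median are scaled by a robust SD (the 68.27th percentile of absolute
#' residuals, small-sample corrected), converted to two-sided t-tail
#' p-values, and screened by a Benjamini-Hochberg step at rate `Q`
#' (Q = 0.001 is the "0.1%" tuning used throughout).
#'
#' @param x numeric sample, n >= 3.
#' @param Q maximum desired false-outlier rate (default 0.001).
#' @return list: clean (x without outliers), outliers (indices into x),
#'   threshold info.
#' @export
routOutliers <- function(x, Q = 0.001) {
  n <- length(x)
  if (n < 3) stop("ROUT needs at least 3 observations")
  res <- x - median(x)
  p68 <- as.numeric(quantile(abs(res), 0.6827))
  rsdr <- p68 * n / (n - 1)
  if (rsdr == 0) return(list(clean = x, outliers = integer(0), rsdr = 0))
  tstat <- abs(res) / rsdr
  pv <- 2 * pt(-tstat, df = n - 1)
  flag <- .bhReject(pv, Q)
  list(clean = x[!flag], outliers = which(flag), rsdr = rsdr)
}

.bhReject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  thr <- q * seq_len(m) / m
  k <- suppressWarnings(max(which(p[o] <= thr)))
  rej <- rep(FALSE, m)
  if (is.finite(k)) rej[o[seq_len(k)]] <- TRUE
  rej
}

#' Spearman rank correlation
#'
#' Average ranks for ties; exact p for n <= 9 (no ties), t approximation
#' otherwise. A constant input yields a flagged missing result.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list: rho, p_value, n, method; `flagged = TRUE` when degenerate.
#' @export
spearmanCorr <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "Spearman", flagged = TRUE))
  exact <- n <= 9 && !anyDuplicated(x) && !anyDuplicated(y)
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = n,
       method = "Spearman", flagged = FALSE)
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Two-sided exact p by hypergeometric enumeration.
#'
#' @param tab 2 x 2 matrix of nonnegative integer counts.
#' @return list: p_value, odds_ratio, method.
#' @export
fishersExact <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cells must be nonnegative integers")
  ht <- fisher.test(tab)
  list(p_value = ht$p.value, odds_ratio = unname(ht$estimate),
       method = "Fisher's exact")
}

#' Cohen's d from summary statistics
#'
#' Standardized group difference computed from means and SDs. The default
#' "rms" variant divides |m1 - m2| by the root-mean-square of the two SDs,
#' sqrt((s1^2 + s2^2)/2); "pooled" uses the df-weighted pooled SD.
#'
#' @param m1,s1,n1 mean, SD and n of group 1.
#' @param m2,s2,n2 mean, SD and n of group 2.
#' @param variant "rms" (default) or "pooled".
#' @return numeric scalar d (nonnegative).
#' @examples
#' cohensDSummary(0.8429, 0.1062, 19, 0.7590, 0.1650, 18)  # 0.6047
#' @export
cohensDSummary <- function(m1, s1, n1, m2, s2, n2,
                           variant = c("rms", "pooled")) {
  variant <- match.arg(variant)
  if (s1 <= 0 || s2 <= 0) stop("SDs must be positive")
  s <- switch(variant,
    rms = sqrt((s1^2 + s2^2) / 2),
    pooled = sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)))
  abs(m1 - m2) / s
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up BH q-values (monotone) with rejection flags at level `q`.
#'
#' @param p p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return list: q_values, reject (logical).
#' @export
fdrBh <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  qv <- p.adjust(p, method = "BH")
  list(q_values = qv, reject = qv < q)
}
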