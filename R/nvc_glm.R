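# Neurovascular-coupling GLM: subject-level betas per channel/chromophore/
# condition, and group-level mixed-effects contrasts with channel-wise
# Benjamini-Hochberg FDR.

#' First-level GLM on a preprocessed chromophore series
#'
#' Ordinary least squares per channel and chromophore on AR-prewhitened data:
#' the DCT projection recorded in the series' provenance is applied to the
#' design, an AR(p) model (AIC, p <= `orderMax`) is fitted to the OLS
#' residuals, and both series and design are filtered before the final fit.
#' Returns one row per (subject, channel, chromophore, condition).
#'
#' @param series a [ChromophoreSeries-class] on the NVC branch (DCT-filtered).
#' @param design a `TaskDesign` or a prebuilt design matrix (time x
#'   conditions, labeled columns).
#' @param subjectId subject identifier carried into the beta table.
#' @param orderMax maximum AR order for prewhitening.
#' @param channels optional subset of channel labels to fit.
#' @return data.frame (`BetaTable`): subject_id, channel, chromophore,
#'   condition, beta, se, dof.
#' @export
firstLevel <- function(series, design, subjectId = "S01", orderMax = 4,
                       channels = NULL) {
  stopifnot(is(series, "ChromophoreSeries"))
  nT <- ncol(series@hbo)
  X <- if (inherits(design, "TaskDesign"))
    buildDesign(design, series@fsHz, nT) else as.matrix(design)
  if (is.null(colnames(X))) stop("design matrix must have labeled columns")
  if (nrow(X) != nT) stop("series and design must share the time axis")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  dctSpec <- grep("^dct:", series@filters, value = TRUE)
  if (length(dctSpec))
    X <- .dctProject(X, series@fsHz, as.numeric(sub("^dct:", "", dctSpec[1])))
  labels <- series@channels
  if (is.null(channels)) channels <- labels
  out <- vector("list", 2 * length(channels))
  k <- 0
  for (chrom in c("HbO", "HbR")) {
    M <- if (chrom == "HbO") series@hbo else series@hbr
    for (ch in channels) {
      y <- M[match(ch, labels), ]
      w <- prewhiten(y, X, orderMax = orderMax)
      fit <- lm.fit(w$X, w$y)
      dof <- length(y) - ncol(X)
      rss <- sum(fit$residuals^2)
      XtXinv <- chol2inv(chol(crossprod(w$X)))
      se <- sqrt(pmax(diag(XtXinv) * rss / dof, 1e-300))
      k <- k + 1
      out[[k]] <- data.frame(subject_id = subjectId, channel = ch,
                             chromophore = chrom, condition = colnames(X),
                             beta = unname(fit$coefficients), se = se,
                             dof = dof, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

.contrastWeights <- function(cellNames, contrast) {
  w <- setNames(numeric(length(cellNames)), cellNames)
  missing <- setdiff(names(contrast), cellNames)
  if (length(missing))
    stop("contrast names not among model cells: ", paste(missing, collapse = ", "))
  w[names(contrast)] <- contrast
  w
}

#' Second-level mixed-effects contrast across subjects
#'
#' Per channel, fits the mixed model beta ~ -1 + Group:condition +
#' (1 | subject) by REML (one fixed-effect cell per group-by-condition
#' combination, a random subject intercept) and evaluates the supplied
#' contrast by a t-test with Satterthwaite degrees of freedom. Channel-wise
#' p-values are converted to q-values by the Benjamini-Hochberg procedure;
#' channels are significant at q < `qThreshold`. Channels whose fit fails are
#' flagged and excluded from the FDR family.
#'
#' @param betas a BetaTable from [firstLevel()] (rows for several subjects).
#' @param cohort cohort table with columns subject_id and group.
#' @param contrast named numeric weights over cells "GROUP:condition", e.g.
#'   `c("MCI:2b" = 1, "CN:2b" = -1)`.
#' @param chromophore chromophore to analyze (default "HbO").
#' @param qThreshold FDR significance level (default 0.05).
#' @return data.frame (`ContrastMap`): channel, estimate, t_stat, df,
#'   p_value, q_value, significant, failed.
#' @export
secondLevel <- function(betas, cohort, contrast, chromophore = "HbO",
                        qThreshold = 0.05) {
  b <- betas[betas$chromophore == chromophore,
             c("subject_id", "channel", "condition", "beta")]
  if (!nrow(b)) stop("no rows for chromophore ", chromophore)
  b <- merge(b, cohort[, c("subject_id", "group")], by = "subject_id")
  if (length(unique(b$group)) < 1) stop("cohort has no groups")
  if (any(table(unique(b[, c("subject_id", "group")])$group) < 2) &&
      length(unique(b$group)) == 2 && any(grepl(":", names(contrast))))
    warning("fewer than 2 subjects in a group; contrasts may be unstable")
  b$cell <- factor(paste(b$group, b$condition, sep = ":"))
  b$subject <- factor(b$subject_id)
  channels <- unique(b$channel)
  res <- data.frame(channel = channels, estimate = NA_real_, t_stat = NA_real_,
                    df = NA_real_, p_value = NA_real_, q_value = NA_real_,
                    significant = FALSE, failed = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(channels)) {
    di <- b[b$channel == channels[i], ]
    fit <- tryCatch(
      withCallingHandlers(
        suppressMessages(lmerTest::lmer(
          beta ~ -1 + cell + (1 | subject), data = di,
          control = lme4::lmerControl(calc.derivs = FALSE,
                                      check.conv.singular = "ignore"))),
        warning = function(w) {
          # routine boundary/convergence chatter from bulk channel fits
          if (grepl("converge|singular|eigenvalue", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit)) { res$failed[i] <- TRUE; next }
    cells <- sub("^cell", "", names(lme4::fixef(fit)))
    w <- tryCatch(.contrastWeights(cells, contrast), error = function(e) NULL)
    if (is.null(w)) stop("contrast cells absent from the fitted model for channel ",
                         channels[i])
    if (all(w == 0)) {   # null contrast: identically zero statistic
      res$estimate[i] <- 0; res$t_stat[i] <- 0
      res$df[i] <- NA_real_; res$p_value[i] <- 1
      next
    }
    ct <- tryCatch(lmerTest::contest1D(fit, unname(w)), error = function(e) NULL)
    if (is.null(ct)) { res$failed[i] <- TRUE; next }
    res$estimate[i] <- ct$Estimate
    res$t_stat[i] <- ct$`t value`
    res$df[i] <- ct$df
    res$p_value[i] <- ct$`Pr(>|t|)`
  }
  ok <- !res$failed
  if (any(ok)) {
    res$q_value[ok] <- p.adjust(res$p_value[ok], method = "BH")
    res$significant[ok] <- res$q_value[ok] < qThreshold
  }
  attr(res, "contrast") <- contrast
  res
}

#' Cognitive-load contrast (2b + 1b) - 0-back
#'
#' Convenience wrapper around [secondLevel()] applying the load weights
#' \{2b: +1, 1b: +1, 0-back: -2\} within one group, or the MCI - CN
#' difference of the two within-group load contrasts.
#'
#' @param betas BetaTable.
#' @param cohort cohort table.
#' @param group "CN", "MCI", or "difference" (MCI minus CN).
#' @param zeroBack which 0-back regressor anchors the baseline (default
#'   "0b_2"; "0b_1" or "mean" of the two are available).
#' @param ... passed to [secondLevel()].
#' @return a ContrastMap (see [secondLevel()]).
#' @export
cognitiveLoadContrast <- function(betas, cohort,
                                  group = c("difference", "CN", "MCI"),
                                  zeroBack = c("0b_2", "0b_1", "mean"), ...) {
  group <- match.arg(group)
  zeroBack <- match.arg(zeroBack)
  need <- c("1b", "2b", if (zeroBack == "mean") c("0b_1", "0b_2") else zeroBack)
  have <- unique(betas$condition)
  if (!all(need %in% have))
    stop("missing condition(s): ", paste(setdiff(need, have), collapse = ", "))
  loadW <- function(g) {
    w <- c(1, 1)
    names(w) <- paste(g, c("2b", "1b"), sep = ":")
    if (zeroBack == "mean") {
      w2 <- c(-1, -1); names(w2) <- paste(g, c("0b_1", "0b_2"), sep = ":")
    } else {
      w2 <- -2; names(w2) <- paste(g, zeroBack, sep = ":")
    }
    c(w, w2)
  }
  contrast <- switch(group,
    CN = loadW("CN"), MCI = loadW("MCI"),
    difference = c(loadW("MCI"), -loadW("CN")))
  secondLevel(betas, cohort, contrast, ...)
}

#' Subject-level LDLPFC average of NVC betas
#'
#' Mean HbO beta over the three LDLPFC channels (F3-F5, F3-F1, F3-FC3),
#' averaged across the selected conditions (the whole paradigm by default).
#' A subject missing any LDLPFC channel is an exclusion error, mirroring the
#' quality rule that all three channels must survive screening.
#'
#' @param betas BetaTable.
#' @param montage montage supplying the LDLPFC label set.
#' @param chromophore default "HbO".
#' @param conditions conditions to average; `NULL` = all present.
#' @return data.frame: subject_id, ldlpfc_beta.
#' @export
ldlpfcAverage <- function(betas, montage, chromophore = "HbO",
                          conditions = NULL) {
  ldl <- ldlpfcChannels(montage)
  b <- betas[betas$chromophore == chromophore & betas$channel %in% ldl, ]
  if (is.null(conditions)) conditions <- unique(b$condition)
  b <- b[b$condition %in% conditions, ]
  subj <- unique(betas$subject_id)
  out <- data.frame(subject_id = subj, ldlpfc_beta = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(subj)) {
    bi <- b[b$subject_id == subj[i], ]
    if (length(unique(bi$channel)) < length(ldl))
      stop("subject ", subj[i], " is missing LDLPFC channel(s); excluded by the quality rule")
    out$ldlpfc_beta[i] <- mean(bi$beta)
  }
  out
}
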