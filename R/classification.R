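# MCI classification protocol: feature assembly, LOOCV random-forest Gini
# importance, top-k selection (k = 3), single-split evaluation with 500
# trees, and 100 repeated train/test splits. Standardization and one-hot
# encoding are fitted on training folds only (no information leakage).

.featureOrder <- c("ldlpfc_nvc_beta", "ceev_ratio", "wd_ldp", "d_ldp",
                   "d_bar", "wd_bar", "age", "sex", "hypertension",
                   "depression_prior")

#' Assemble the subject-level feature matrix
#'
#' Joins the pipeline's subject-level outputs — task-averaged LDLPFC NVC
#' beta, CEEV ratio (%), task-averaged connectivity metrics — with cohort
#' covariates (age, sex, hypertension, prior depression) by subject id.
#' Subjects with any missing feature are dropped and named in a message.
#'
#' @param nvc data.frame subject_id, ldlpfc_beta (from [ldlpfcAverage()]).
#' @param fc data.frame subject_id, d_bar, wd_bar, d_ldp, wd_ldp
#'   (task-averaged).
#' @param ev data.frame subject_id, ceev_ratio (%).
#' @param cohort cohort table.
#' @return data.frame (`FeatureMatrix`) with the feature columns, `label`
#'   (factor CN/MCI) and rownames = subject ids; attribute `dropped` lists
#'   excluded subjects.
#' @export
assembleFeatures <- function(nvc, fc, ev, cohort) {
  df <- merge(cohort[, c("subject_id", "group", "age", "sex", "hypertension",
                         "depression_prior")],
              setNames(nvc[, c("subject_id", "ldlpfc_beta")],
                       c("subject_id", "ldlpfc_nvc_beta")), by = "subject_id")
  df <- merge(df, fc, by = "subject_id")
  feats <- .featureOrder
  if (is.null(ev)) feats <- setdiff(feats, "ceev_ratio")
  else df <- merge(df, setNames(ev[, c("subject_id", "ceev_ratio")],
                                c("subject_id", "ceev_ratio")),
                   by = "subject_id")
  all_ids <- cohort$subject_id
  keep <- complete.cases(df[, feats])
  dropped <- c(setdiff(all_ids, df$subject_id), df$subject_id[!keep])
  if (length(dropped))
    message("dropping incomplete subject(s): ", paste(dropped, collapse = ", "))
  df <- df[keep, ]
  if (!nrow(df)) stop("no complete subjects to assemble")
  out <- df[, feats]
  out$sex <- factor(df$sex, levels = c("F", "M"))
  out$hypertension <- factor(df$hypertension, levels = c(FALSE, TRUE))
  out$depression_prior <- factor(df$depression_prior, levels = c(FALSE, TRUE))
  out$label <- factor(df$group, levels = c("CN", "MCI"))
  rownames(out) <- df$subject_id
  out <- out[order(rownames(out)), ]
  attr(out, "dropped") <- dropped
  out
}

# fit standardization/encoding on train rows; apply to any rows
.fitPreproc <- function(train) {
  num <- names(train)[vapply(train, is.numeric, TRUE)]
  list(num = num,
       center = vapply(train[num], mean, numeric(1)),
       scale = vapply(train[num], function(v) {
         s <- sd(v); if (s == 0) 1 else s }, numeric(1)))
}

.applyPreproc <- function(pp, data) {
  out <- lapply(names(data), function(nm) {
    v <- data[[nm]]
    if (nm %in% pp$num)
      return(setNames(data.frame((v - pp$center[nm]) / pp$scale[nm]), nm))
    lv <- levels(v)
    oh <- vapply(lv, function(l) as.numeric(v == l), numeric(length(v)))
    if (length(v) == 1) oh <- matrix(oh, nrow = 1, dimnames = list(NULL, lv))
    colnames(oh) <- paste(nm, lv, sep = ".")
    as.data.frame(oh)
  })
  out <- do.call(cbind, out)
  rownames(out) <- rownames(data)
  out
}

.foldImportance <- function(xTrain, yTrain, nTrees) {
  rf <- randomForest::randomForest(x = xTrain, y = yTrain, ntree = nTrees,
                                   importance = FALSE)
  imp <- randomForest::importance(rf, type = 2)[, 1]
  if (sum(imp) > 0) imp <- imp / sum(imp)
  imp
}

.collapseEncoded <- function(imp, features) {
  # one-hot columns "feat.level" fold back onto their source feature
  out <- setNames(numeric(length(features)), features)
  for (nm in names(imp)) {
    src <- if (nm %in% features) nm else sub("\\.[^.]*$", "", nm)
    out[src] <- out[src] + imp[nm]
  }
  out
}

#' LOOCV random-forest feature importance
#'
#' For each of the n leave-one-out folds, fits a random forest on the
#' remaining n - 1 subjects (standardization and one-hot encoding fitted
#' within the fold), records the forest's Gini importances normalized to sum
#' to one, folds one-hot columns back onto their source features, and
#' returns the per-feature mean across folds.
#'
#' @param features FeatureMatrix from [assembleFeatures()].
#' @param nTrees trees per forest (default 500).
#' @param seed RNG seed.
#' @return named numeric vector of mean importances (feature order fixed);
#'   attribute `folds` gives the per-fold matrix.
#' @export
loocvImportance <- function(features, nTrees = 500, seed = 1) {
  stopifnot(nrow(features) >= 3)
  set.seed(seed)
  y <- features$label
  x <- features[, setdiff(names(features), "label")]
  feats <- names(x)
  n <- nrow(x)
  impM <- matrix(NA_real_, n, length(feats), dimnames = list(NULL, feats))
  for (i in seq_len(n)) {
    yTr <- y[-i]
    if (nlevels(droplevels(yTr)) < 2) {
      warning("fold ", i, " has a single class; skipped")
      next
    }
    pp <- .fitPreproc(x[-i, ])
    xTr <- .applyPreproc(pp, x[-i, ])
    imp <- .foldImportance(xTr, yTr, nTrees)
    impM[i, ] <- .collapseEncoded(imp, feats)
  }
  res <- colMeans(impM, na.rm = TRUE)
  attr(res, "folds") <- impM
  res
}

#' Select the k most important features
#'
#' Highest mean importance wins; ties break by the fixed feature order of
#' the matrix (first listed wins).
#'
#' @param importances named importances from [loocvImportance()].
#' @param k number of features (default 3).
#' @return character vector of k feature names.
#' @export
selectTopK <- function(importances, k = 3) {
  if (k > length(importances)) stop("k exceeds the number of scored features")
  names(importances)[order(-importances, seq_along(importances))][seq_len(k)]
}

.stratifiedSplit <- function(y, trainFrac) {
  idx <- unlist(lapply(levels(y), function(l) {
    rows <- which(y == l)
    sample(rows, max(1, round(trainFrac * length(rows))))
  }))
  sort(idx)
}

#' Evaluate a single stratified train/test split
#'
#' Stratified `trainFrac` split; random forest with `nTrees` trees on the
#' selected features (preprocessing fitted on the training part); accuracy,
#' support-weighted precision and recall on the test part; F1 as the
#' harmonic mean of that precision/recall pair.
#'
#' @param features FeatureMatrix.
#' @param selected feature names to use.
#' @param trainFrac training fraction (default 0.8).
#' @param nTrees trees (default 500).
#' @param seed RNG seed.
#' @return list: accuracy, precision, recall, f1, n_train, n_test.
#' @export
evaluateSplit <- function(features, selected, trainFrac = 0.8, nTrees = 500,
                          seed = 1) {
  set.seed(seed)
  y <- features$label
  x <- features[, selected, drop = FALSE]
  tr <- .stratifiedSplit(y, trainFrac)
  te <- setdiff(seq_len(nrow(x)), tr)
  if (nlevels(droplevels(y[tr])) < 2) stop("single-class training set")
  if (length(te) == 0 || nlevels(droplevels(y[te])) < 2)
    stop("single-class (or empty) test set")
  pp <- .fitPreproc(x[tr, , drop = FALSE])
  rf <- randomForest::randomForest(x = .applyPreproc(pp, x[tr, , drop = FALSE]),
                                   y = y[tr], ntree = nTrees)
  pred <- predict(rf, .applyPreproc(pp, x[te, , drop = FALSE]))
  obs <- y[te]
  acc <- mean(pred == obs)
  levs <- levels(y)
  prec <- rec <- setNames(numeric(length(levs)), levs)
  for (l in levs) {
    tp <- sum(pred == l & obs == l)
    prec[l] <- if (sum(pred == l) == 0) 0 else tp / sum(pred == l)
    rec[l] <- if (sum(obs == l) == 0) 0 else tp / sum(obs == l)
  }
  wt <- as.numeric(table(obs)[levs]) / length(obs)
  precision <- sum(wt * prec)
  recall <- sum(wt * rec)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(accuracy = acc, precision = precision, recall = recall, f1 = f1,
       n_train = length(tr), n_test = length(te))
}

#' Repeated train/test split evaluation
#'
#' `nRuns` stratified splits with distinct seeds derived from the master
#' seed; mean and SD of test accuracy. Runs that fail (e.g. a degenerate
#' test set) are excluded and counted.
#'
#' @param features FeatureMatrix.
#' @param selected feature names.
#' @param nRuns number of splits (default 100).
#' @param trainFrac,nTrees as in [evaluateSplit()].
#' @param seed master seed.
#' @return list: mean_accuracy, sd_accuracy, accuracies, n_failed.
#' @export
repeatedSplits <- function(features, selected, nRuns = 100, trainFrac = 0.8,
                           nTrees = 500, seed = 1) {
  accs <- rep(NA_real_, nRuns)
  for (r in seq_len(nRuns)) {
    res <- tryCatch(evaluateSplit(features, selected, trainFrac, nTrees,
                                  seed = .deriveSeed(seed, 1000L + r)),
                    error = function(e) NULL)
    if (!is.null(res)) accs[r] <- res$accuracy
  }
  ok <- !is.na(accs)
  list(mean_accuracy = mean(accs[ok]), sd_accuracy = sd(accs[ok]),
       accuracies = accs, n_failed = sum(!ok))
}
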