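# Per-band KNN emotion classification: neighbor voting with z-scored
# Euclidean distances, stratified cross-validation, confusion-matrix
# evaluation, one-vs-rest ROC, and 2-D principal-component projection.

fm_parts <- function(x, labels = NULL) {
  if (inherits(x, "feature_matrix")) {
    list(x = x$features, y = x$labels)
  } else {
    if (is.null(labels)) {
      stop("matrix input requires `labels`", call. = FALSE)
    }
    list(x = as.matrix(x), y = as.character(labels))
  }
}

#' k-nearest-neighbor prediction
#'
#' Features are z-scored with means/SDs fit on the training rows only
#' (zero-variance columns are left unscaled); distances are Euclidean.
#' The predicted label is the majority class among the `k` nearest training
#' rows; when classes tie in votes the class of the nearest neighbor among
#' the tied classes wins. Per-class scores are the fraction of the `k`
#' neighbors belonging to each class.
#'
#' @param train a [build_feature_matrix()] result, or a numeric matrix with
#'   `train_labels`.
#' @param test feature matrix of the same column layout.
#' @param k number of neighbors (`1 <= k <= nrow(train)`).
#' @param train_labels class labels when `train` is a plain matrix.
#' @return list with `labels` (character) and `scores` (rows = test points,
#'   columns = classes, vote fractions in `[0, 1]`).
#' @export
knn_predict <- function(train, test, k = 5, train_labels = NULL) {
  tr <- fm_parts(train, train_labels)
  te <- fm_parts(test, labels = rep(NA_character_, 1))
  if (ncol(tr$x) != ncol(te$x)) {
    stop("train and test must have identical column layout", call. = FALSE)
  }
  if (any(!is.finite(tr$x)) || any(!is.finite(te$x))) {
    stop("non-finite feature values", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  if (k > nrow(tr$x)) {
    stop(sprintf("k = %d exceeds the training-set size %d", k, nrow(tr$x)),
         call. = FALSE)
  }
  ctr <- colMeans(tr$x)
  scl <- apply(tr$x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  ztr <- scale(tr$x, center = ctr, scale = scl)
  zte <- scale(te$x, center = ctr, scale = scl)
  classes <- sort(unique(tr$y))
  n_te <- nrow(zte)
  labels <- character(n_te)
  scores <- matrix(0, n_te, length(classes),
                   dimnames = list(NULL, classes))
  for (i in seq_len(n_te)) {
    d <- sqrt(colSums((t(ztr) - zte[i, ])^2))
    ord <- order(d)          # stable: ties keep training order
    nb <- ord[seq_len(k)]
    votes <- table(factor(tr$y[nb], levels = classes))
    scores[i, ] <- as.numeric(votes) / k
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) {
      labels[i] <- top
    } else {
      # tie-break: the tied class holding the single nearest neighbor
      labels[i] <- tr$y[nb[min(which(tr$y[nb] %in% top))]]
    }
  }
  list(labels = labels, scores = scores)
}

stratified_folds <- function(labels, folds, seed) {
  if (folds < 2) stop("`folds` must be >= 2", call. = FALSE)
  assignment <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

#' Stratified cross-validated KNN
#'
#' Splits epochs into stratified folds (seeded), predicts each fold from the
#' others, and pools the held-out predictions into one evaluation.
#'
#' @param features a [build_feature_matrix()] result.
#' @param k number of neighbors.
#' @param folds number of folds (>= 2).
#' @param seed fold-assignment seed.
#' @return list with `report` (a [evaluate()] result augmented with ROC/AUC),
#'   `predictions`, `scores`, `fold`.
#' @export
cv_knn <- function(features, k = 5, folds = 5, seed = 1) {
  p <- fm_parts(features)
  fold <- stratified_folds(p$y, folds, seed)
  classes <- sort(unique(p$y))
  pred <- character(length(p$y))
  scores <- matrix(NA_real_, length(p$y), length(classes),
                   dimnames = list(NULL, classes))
  for (f in seq_len(folds)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    res <- knn_predict(p$x[tr, , drop = FALSE], p$x[te, , drop = FALSE],
                       k = k, train_labels = p$y[tr])
    pred[te] <- res$labels
    scores[te, colnames(res$scores)] <- res$scores
  }
  report <- evaluate(p$y, pred)
  roc <- if (length(classes) > 1) one_vs_rest_roc(p$y, scores) else NULL
  report$roc <- roc$roc
  report$auc <- roc$auc
  list(report = report, predictions = pred, scores = scores, fold = fold)
}

#' Choose k by stratified cross-validation
#'
#' Scores every candidate neighbor count by pooled cross-validated accuracy
#' and returns the best; ties go to the smallest k.
#'
#' @param features a [build_feature_matrix()] result.
#' @param candidates integer vector of candidate k values.
#' @param folds number of folds (>= 2).
#' @param seed fold-assignment seed (folds are shared across candidates).
#' @return list with `k` (chosen) and `accuracy` (named per-candidate
#'   pooled CV accuracy, fractions).
#' @export
select_k <- function(features, candidates = c(1, 3, 5, 7, 9), folds = 5,
                     seed = 1) {
  if (length(candidates) < 1L) {
    stop("`candidates` must be non-empty", call. = FALSE)
  }
  p <- fm_parts(features)
  fold <- stratified_folds(p$y, folds, seed)
  min_train <- min(vapply(seq_len(folds),
                          function(f) sum(fold != f), integer(1)))
  if (any(candidates > min_train)) {
    stop(sprintf("candidate k exceeds the smallest training-fold size (%d)",
                 min_train), call. = FALSE)
  }
  acc <- vapply(candidates, function(k) {
    pred <- character(length(p$y))
    for (f in seq_len(folds)) {
      te <- which(fold == f)
      tr <- which(fold != f)
      pred[te] <- knn_predict(p$x[tr, , drop = FALSE],
                              p$x[te, , drop = FALSE],
                              k = k, train_labels = p$y[tr])$labels
    }
    mean(pred == p$y)
  }, numeric(1))
  names(acc) <- as.character(candidates)
  best <- candidates[acc == max(acc)]
  list(k = min(best), accuracy = acc)
}

#' Confusion-matrix evaluation
#'
#' Builds the true-by-predicted count matrix and derives per-class
#' true-positive rates (percent of each class's true samples classified
#' correctly) and overall accuracy (percent, `100 * trace / total`).
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param levels class alphabet; defaults to the sorted classes present in
#'   `true_labels`. A predicted label outside the alphabet is an error.
#' @return object of class `classification_report`: list with `confusion`,
#'   `class_n`, `tp_rate`, `overall_accuracy`.
#' @export
evaluate <- function(true_labels, predicted_labels, levels = NULL) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (length(true_labels) == 0L) stop("no labels to evaluate", call. = FALSE)
  if (is.null(levels)) levels <- sort(unique(true_labels))
  bad <- setdiff(unique(c(true_labels, predicted_labels)), levels)
  if (length(bad) > 0) {
    stop("label(s) outside the class alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tf <- factor(true_labels, levels = levels)
  pf <- factor(predicted_labels, levels = levels)
  confusion <- table(true = tf, predicted = pf)
  class_n <- rowSums(confusion)
  tp_rate <- ifelse(class_n > 0, 100 * diag(confusion) / class_n, NA_real_)
  structure(
    list(confusion = unclass(confusion),
         class_n = class_n,
         tp_rate = tp_rate,
         overall_accuracy = 100 * sum(diag(confusion)) / sum(confusion)),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> overall accuracy %.1f%%\n",
              x$overall_accuracy))
  print(x$confusion)
  cat("per-class TP rate (%):\n")
  print(round(x$tp_rate, 1))
  if (!is.null(x$auc)) {
    cat("one-vs-rest AUC:\n")
    print(round(x$auc, 3))
  }
  invisible(x)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, sweeps a threshold over the distinct values of that
#' class's score column (positive = score >= threshold), recording
#' (FPR, TPR) points from (0, 0) to (1, 1), and integrates the curve by the
#' trapezoidal rule.
#'
#' @param true_labels label vector.
#' @param scores matrix of per-class scores in `[0, 1]`, columns named by
#'   class.
#' @return list with `roc` (per-class data.frames of `threshold`, `fpr`,
#'   `tpr`) and `auc` (named numeric).
#' @export
one_vs_rest_roc <- function(true_labels, scores) {
  true_labels <- as.character(true_labels)
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) {
    stop("`scores` must have class-named columns", call. = FALSE)
  }
  if (nrow(scores) != length(true_labels)) {
    stop("`scores` rows must align with labels", call. = FALSE)
  }
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1)) {
    stop("scores must be finite and in [0, 1]", call. = FALSE)
  }
  roc <- list()
  auc <- stats::setNames(numeric(0), character(0))
  for (cl in colnames(scores)) {
    pos <- true_labels == cl
    if (all(pos) || !any(pos)) {
      stop(sprintf(
        "ROC undefined for class '%s': needs both positives and negatives",
        cl), call. = FALSE)
    }
    s <- scores[, cl]
    thr <- c(Inf, sort(unique(s), decreasing = TRUE))
    pts <- t(vapply(thr, function(t0) {
      pred_pos <- s >= t0
      c(fpr = sum(pred_pos & !pos) / sum(!pos),
        tpr = sum(pred_pos & pos) / sum(pos))
    }, numeric(2)))
    curve <- data.frame(threshold = thr, fpr = pts[, "fpr"],
                        tpr = pts[, "tpr"])
    if (curve$fpr[nrow(curve)] < 1 || curve$tpr[nrow(curve)] < 1) {
      curve <- rbind(curve, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
    }
    a <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
    roc[[cl]] <- curve
    auc[cl] <- a
  }
  list(roc = roc, auc = auc)
}

#' 2-D principal-component projection
#'
#' Projects standardized features onto their top-2 variance axes
#' (orthonormal loadings), the usual scatter-plot view of the feature space.
#'
#' @param features a [build_feature_matrix()] result or numeric matrix
#'   (>= 3 rows, >= 2 columns).
#' @return list with `coords` (n x 2 scores), `axes` (p x 2 orthonormal
#'   loadings), `sdev` (component standard deviations), `labels` (when the
#'   input carries labels).
#' @export
project_2d <- function(features) {
  labels <- NULL
  if (inherits(features, "feature_matrix")) {
    labels <- features$labels
    x <- features$features
  } else {
    x <- as.matrix(features)
  }
  if (nrow(x) < 3L || ncol(x) < 2L) {
    stop("projection needs at least 3 rows and 2 columns", call. = FALSE)
  }
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  z <- scale(x, scale = scl)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  if (sum(pc$sdev > 1e-10) < 2L) {
    stop("degenerate projection: feature matrix has rank < 2", call. = FALSE)
  }
  list(coords = pc$x[, 1:2, drop = FALSE],
       axes = pc$rotation[, 1:2, drop = FALSE],
       sdev = pc$sdev, labels = labels)
}

#' Per-band classification comparison
#'
#' The full per-band pipeline on a set of labeled recordings: condition each
#' recording (baseline, band-pass, notch), pool fixed 1-s epochs, reject
#' over-threshold epochs, compute sample entropy once, then per band build
#' the (SampEn, band-PSD) feature matrix and run stratified cross-validated
#' KNN. Emits one report per band and a summary accuracy table.
#'
#' @param recordings list of labeled [eeg_recording()] objects (>= 2
#'   classes).
#' @param bands character vector of band names (default all five).
#' @param channels feature channels (default `c("T7", "T8")`).
#' @param spec a [filter_spec()].
#' @param notch_bandwidth notch width, Hz.
#' @param window_length epoch length, seconds.
#' @param amplitude_limit rejection threshold, microvolts (`Inf` disables).
#' @param k,folds,seed KNN and cross-validation settings.
#' @param m,r sample-entropy parameters.
#' @return list with `summary` (data.frame: band, n_epochs, accuracy_pct,
#'   mean_auc) and `reports` (named list of per-band reports).
#' @export
run_band_comparison <- function(recordings,
                                bands = eeg_bands()$name,
                                channels = c("T7", "T8"),
                                spec = filter_spec(),
                                notch_bandwidth = 2,
                                window_length = 1,
                                amplitude_limit = 100,
                                k = 5, folds = 5, seed = 1,
                                m = 2, r = 0.2) {
  stopifnot(length(recordings) >= 1)
  labels <- vapply(recordings, `[[`, character(1), "state_label")
  if (length(unique(labels)) < 2L) {
    stop("need recordings from at least 2 classes", call. = FALSE)
  }
  for (b in bands) band_definition(b)  # validate before any computation
  sets <- lapply(seq_along(recordings), function(i) {
    es <- preprocess_recording(recordings[[i]], spec, notch_bandwidth,
                               window_length)
    es$source_ids <- rep(paste0("rec", i), length(es$epochs))
    es
  })
  pooled <- combine_epoch_sets(sets)
  if (is.finite(amplitude_limit)) {
    pooled <- reject_artifact_epochs(pooled, amplitude_limit)
  }
  sampen <- epoch_sampen(pooled, channels, m, r)
  reports <- list()
  rows <- list()
  for (b in bands) {
    fm <- build_feature_matrix(pooled, channels, b, m, r, sampen = sampen)
    res <- tryCatch(cv_knn(fm, k = k, folds = folds, seed = seed),
                    error = function(e) {
                      stop(sprintf("band '%s': %s", b, conditionMessage(e)),
                           call. = FALSE)
                    })
    reports[[b]] <- res$report
    rows[[b]] <- data.frame(
      band = b,
      n_epochs = nrow(fm$features),
      accuracy_pct = res$report$overall_accuracy,
      mean_auc = mean(res$report$auc),
      stringsAsFactors = FALSE
    )
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       reports = reports)
}
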