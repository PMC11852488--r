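# Brute-force oracles, written independently of the package implementation
# and kept deliberately naive: exhaustive enumeration with explicit loops.

# Sample entropy by exhaustive template-pair counting (Chebyshev distance,
# self-matches excluded, unordered pairs counted once, templates i = 1..N-m
# for both lengths). Returns NA when no length-m pair matches.
sampen_oracle <- function(x, m, tol) {
  N <- length(x)
  nt <- N - m
  A <- 0
  B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- 0
      for (u in 0:(m - 1)) {
        dm <- max(dm, abs(x[i + u] - x[j + u]))
      }
      if (dm <= tol) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= tol) A <- A + 1
      }
    }
  }
  if (B == 0) return(NA_real_)
  if (A == 0) return(Inf)
  -log(A / B)
}

# KNN by exhaustive all-pairs distance enumeration on z-scored features
# (train statistics), majority vote, ties broken by the class of the
# nearest neighbor among the tied classes.
knn_oracle <- function(train_x, train_y, test_x, k) {
  ctr <- colMeans(train_x)
  scl <- apply(train_x, 2, sd)
  scl[scl == 0] <- 1
  out <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d <- numeric(nrow(train_x))
    for (j in seq_len(nrow(train_x))) {
      d[j] <- sqrt(sum((((train_x[j, ] - ctr) / scl) -
                          ((test_x[i, ] - ctr) / scl))^2))
    }
    nb <- order(d)[seq_len(k)]
    votes <- table(train_y[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) {
      out[i] <- top
    } else {
      for (j in nb) {
        if (train_y[j] %in% top) {
          out[i] <- train_y[j]
          break
        }
      }
    }
  }
  out
}

# AUC by exhaustive threshold enumeration + trapezoid, independent of the
# package's sweep.
auc_oracle <- function(is_pos, score) {
  thr <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  fpr <- numeric(length(thr))
  tpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    fpr[i] <- sum(score >= thr[i] & !is_pos) / sum(!is_pos)
    tpr[i] <- sum(score >= thr[i] & is_pos) / sum(is_pos)
  }
  sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
}

# One-second synthetic epochs packed into an epoch_set without going
# through a recording, for feature-module unit tests.
toy_epoch_set <- function(epoch_list, fs = 128,
                          labels = rep("neutral", length(epoch_list)),
                          channel_labels = c("T7", "T8")) {
  epoch_set(epoch_list, window_length = ncol(epoch_list[[1]]) / fs, fs = fs,
            labels = labels, channel_labels = channel_labels)
}

# Single-channel recording wrapper for filter tests.
one_channel_rec <- function(x, fs, label = "T7") {
  eeg_recording(matrix(x, nrow = 1), fs, label)
}
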