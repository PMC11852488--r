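#!/usr/bin/env Rscript
# Per-band emotion classification: stratified 5-fold cross-validated KNN
# on (SampEn, band-PSD) features for each of the five frequency bands,
# with k selected by cross-validation on the delta band. Writes the
# band-accuracy table and the per-band confusion/ROC report.

suppressMessages(library(eegemotion))
seed <- 1
dir.create("results", showWarnings = FALSE)

recordings <- lapply(c("neutral", "fear", "anger"), function(s) {
  read_eeg(file.path("scratch/eeg", paste0(s, ".csv")))
})

pooled <- combine_epoch_sets(lapply(recordings, preprocess_recording))
pooled <- reject_artifact_epochs(pooled, 100)
fm_delta <- build_feature_matrix(pooled, c("T7", "T8"), "delta")
sel <- select_k(fm_delta, candidates = c(1, 3, 5, 7, 9), seed = seed)
cat("k selection (delta band, pooled CV accuracy):\n")
print(round(sel$accuracy, 4))
cat("chosen k:", sel$k, "\n\n")

cmp <- run_band_comparison(recordings, k = sel$k, folds = 5, seed = seed)
write.csv(cmp$summary, "results/band_accuracy.csv", row.names = FALSE)
cat("Per-band cross-validated accuracy -> results/band_accuracy.csv\n")
print(transform(cmp$summary, accuracy_pct = round(accuracy_pct, 1),
                mean_auc = round(mean_auc, 3)), row.names = FALSE)

best <- cmp$summary$band[which.max(cmp$summary$accuracy_pct)]
cat(sprintf("\nBest band: %s. Its confusion matrix:\n", best))
print(cmp$reports[[best]]$confusion)
jsonlite::write_json(
  lapply(cmp$reports, function(r) {
    list(confusion = r$confusion, tp_rate = r$tp_rate,
         overall_accuracy = r$overall_accuracy, auc = r$auc)
  }),
  "results/classification_report.json", auto_unbox = TRUE, digits = 10)

# 2-D principal-component view of the best band's feature space
fm_best <- build_feature_matrix(pooled, c("T7", "T8"), best)
pr <- project_2d(fm_best)
coords <- data.frame(pr$coords, state = pr$labels)
write.csv(coords, "results/projection_2d.csv", row.names = FALSE)
cat("2-D projection coordinates -> results/projection_2d.csv\n")
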