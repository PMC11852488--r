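#!/usr/bin/env Rscript
# Condition the simulated recordings (baseline correction, 0.5-50 Hz
# zero-phase FIR band-pass, 50 Hz notch, 1-s fixed-window epoching,
# 100 uV threshold rejection) and extract the per-epoch feature matrix
# (sample entropy + delta-band power on T7/T8). Demonstrates on the
# artifact-laden copy that threshold rejection removes the blink epochs.

suppressMessages(library(eegemotion))
dir.create("results", showWarnings = FALSE)

states <- c("neutral", "fear", "anger")
sets <- lapply(states, function(s) {
  preprocess_recording(read_eeg(file.path("scratch/eeg",
                                          paste0(s, ".csv"))))
})
pooled <- combine_epoch_sets(sets)
clean <- reject_artifact_epochs(pooled, amplitude_limit = 100)
cat(sprintf("Pooled %d epochs (%s); %d rejected at 100 uV.\n",
            length(pooled$epochs),
            paste(table(pooled$labels), collapse = "/"),
            sum(attr(clean, "rejection")$rejected)))

noisy <- preprocess_recording(read_eeg("scratch/eeg/neutral_artifacts.csv"))
kept <- reject_artifact_epochs(noisy, amplitude_limit = 100)
rej <- attr(kept, "rejection")
cat(sprintf("Artifact copy: %d of %d epochs rejected (blink epochs).\n",
            sum(rej$rejected), nrow(rej)))

fm <- build_feature_matrix(clean, c("T7", "T8"), "delta")
write.csv(as.data.frame(fm), "results/features_delta.csv",
          row.names = FALSE)
cat("Delta-band feature matrix:", nrow(fm$features), "epochs x",
    ncol(fm$features), "features -> results/features_delta.csv\n")
agg <- aggregate(fm$features, by = list(state = fm$labels), FUN = mean)
print(agg, digits = 3, row.names = FALSE)
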