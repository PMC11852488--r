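#!/usr/bin/env Rscript
# Simulate the EEG arm of the study: one 216-s, 14-channel, 128-Hz
# recording per emotional state (neutral / fear / anger) from the shipped
# state profiles, plus an artifact-laden copy of the neutral recording for
# the preprocessing demonstration. Raw traces are bulky and go to
# scratch/; a small summary table goes to results/.

suppressMessages(library(eegemotion))
seed <- 1
dir.create("scratch/eeg", showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

profiles <- default_profiles()
summary_rows <- list()
for (state in names(profiles)) {
  rec <- generate_recording(profiles[[state]], duration = 216, fs = 128,
                            seed = seed * 100 + match(state, names(profiles)))
  write_eeg_csv(rec, file.path("scratch/eeg", paste0(state, ".csv")))
  summary_rows[[state]] <- data.frame(
    state = state,
    duration_s = rec$duration,
    fs_hz = rec$fs,
    channels = nrow(rec$samples),
    rms_uv = round(mean(apply(rec$samples, 1, function(x) sqrt(mean(x^2)))), 2),
    peak_uv = round(max(abs(rec$samples)), 1)
  )
}

# artifact-laden copy: 12 blinks/min at 400 uV plus a 20 uV 50 Hz line
neutral <- read_eeg("scratch/eeg/neutral.csv")
noisy <- inject_artifacts(neutral, blink_rate = 12, blink_amplitude = 400,
                          line_freq = 50, line_amplitude = 20, seed = seed)
write_eeg_csv(noisy$recording, "scratch/eeg/neutral_artifacts.csv")
writeLines(format(noisy$blink_times, digits = 6),
           "scratch/eeg/neutral_blink_times.txt")

tab <- do.call(rbind, c(summary_rows, list(make.row.names = FALSE)))
write.csv(tab, "results/eeg_simulation_summary.csv", row.names = FALSE)
cat("Simulated", nrow(tab), "recordings (scratch/eeg/):\n")
print(tab, row.names = FALSE)
cat(sprintf("Injected %d blinks into the neutral copy.\n",
            length(noisy$blink_times)))
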