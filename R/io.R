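# Interchange formats: EEG as CSV (rows = time samples, columns = channels)
# with a JSON metadata sidecar, a minimal 16-bit EDF reader/writer, and the
# behavioral trial-table CSV.

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write an EEG recording as CSV plus JSON sidecar
#'
#' CSV: one row per time sample, one column per channel, header = channel
#' labels. Sidecar (same path with `.json` extension): `fs`, `state_label`,
#' `channel_labels`, `schema_version`.
#'
#' @param rec an [eeg_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(rec, path) {
  if (!inherits(rec, "eeg_recording")) {
    stop("`rec` must be an eeg_recording", call. = FALSE)
  }
  df <- as.data.frame(t(rec$samples))
  names(df) <- rec$channel_labels
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(schema_version = 1L, fs = rec$fs,
               state_label = rec$state_label,
               channel_labels = rec$channel_labels)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an EEG recording from CSV plus JSON sidecar
#'
#' The CSV header must be the canonical 14-channel label set or a subset of
#' it. Sampling rate and state label come from the sidecar; a missing
#' sidecar is an error naming the expected path.
#'
#' @param path CSV path written by [write_eeg_csv()].
#' @param fs_expected optional sampling rate to check against; a mismatch
#'   logs a warning and keeps the sidecar value.
#' @return an [eeg_recording()].
#' @export
read_eeg_csv <- function(path, fs_expected = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    stop("missing metadata sidecar; expected it at: ", sp, call. = FALSE)
  }
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  unknown <- setdiff(names(df), eeg_channels())
  if (length(unknown) > 0) {
    stop("CSV header contains non-canonical channel label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(fs_expected) && !isTRUE(all.equal(fs_expected, meta$fs))) {
    warning(sprintf("sampling rate mismatch: sidecar says %g Hz, expected %g Hz",
                    meta$fs, fs_expected))
  }
  eeg_recording(t(as.matrix(df)), meta$fs, names(df),
                if (is.null(meta$state_label)) NA_character_
                else meta$state_label)
}

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop("EDF header field overflow: ", s, call. = FALSE)
  formatC(s, width = -width)
}

num_field <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  pad_field(s, width)
}

#' Write an EEG recording as 16-bit EDF
#'
#' Minimal European Data Format writer: 1-second data records, one signal
#' per channel, physical range taken from the data, digital range the full
#' 16-bit span. The recording length is truncated to whole seconds.
#'
#' @param rec an [eeg_recording()]; `fs` must be a positive integer.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eeg_edf <- function(rec, path) {
  if (!inherits(rec, "eeg_recording")) {
    stop("`rec` must be an eeg_recording", call. = FALSE)
  }
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF export needs an integer fs", call. = FALSE)
  ns <- nrow(rec$samples)
  n_rec <- floor(ncol(rec$samples) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF record", call. = FALSE)
  x <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  # round the physical range outward to 2 decimals so the 8-char header
  # fields carry it exactly and the reader rescales with the same values
  pmin_ <- floor(pmin_ * 100) / 100
  pmax_ <- ceiling(pmax_ * 100) / 100
  dmin <- -32768L
  dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  header_bytes <- 256L + 256L * ns
  wr(pad_field("0", 8))                     # version
  wr(pad_field("synthetic", 80))            # patient id
  wr(pad_field("eegemotion synthetic recording", 80))
  wr(pad_field("01.01.26", 8))              # start date
  wr(pad_field("00.00.00", 8))              # start time
  wr(pad_field(header_bytes, 8))
  wr(pad_field("", 44))
  wr(pad_field(n_rec, 8))
  wr(pad_field("1", 8))                     # record duration, s
  wr(pad_field(ns, 4))
  wr(paste0(vapply(rec$channel_labels, pad_field, "", width = 16),
            collapse = ""))
  wr(strrep(" ", 80 * ns))                  # transducer
  wr(paste0(rep(pad_field("uV", 8), ns), collapse = ""))
  wr(paste0(vapply(pmin_, num_field, "", width = 8), collapse = ""))
  wr(paste0(vapply(pmax_, num_field, "", width = 8), collapse = ""))
  wr(paste0(rep(pad_field(dmin, 8), ns), collapse = ""))
  wr(paste0(rep(pad_field(dmax, 8), ns), collapse = ""))
  wr(strrep(" ", 80 * ns))                  # prefiltering
  wr(paste0(rep(pad_field(fs, 8), ns), collapse = ""))
  wr(strrep(" ", 32 * ns))
  scale_ <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      seg <- x[ch, ((r - 1) * fs + 1):(r * fs)]
      dig <- as.integer(round(dmin + (seg - pmin_[ch]) * scale_[ch]))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a 16-bit EDF file
#'
#' Counterpart of [write_eeg_edf()]. All signals must share one sampling
#' rate; the channel count must be the canonical 14 and the labels a
#' permutation of [eeg_channels()] — they are mapped back to canonical
#' order.
#'
#' @param path EDF path.
#' @param state_label optional class label to attach.
#' @return an [eeg_recording()].
#' @export
read_eeg_edf <- function(path, state_label = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchar_) rawToChar(readBin(con, "raw", nchar_))
  rdn <- function(nchar_) as.numeric(trimws(rd(nchar_)))
  invisible(rd(8 + 80 + 80 + 8 + 8))
  invisible(rdn(8))                         # header bytes
  invisible(rd(44))
  n_rec <- rdn(8)
  rec_dur <- rdn(8)
  ns <- as.integer(rdn(4))
  if (ns != 14L) {
    stop(sprintf("unsupported EDF channel count %d (need the canonical 14)",
                 ns), call. = FALSE)
  }
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  if (!setequal(labels, eeg_channels())) {
    stop("EDF labels are not the canonical 14-channel montage: ",
         paste(labels, collapse = ", "), call. = FALSE)
  }
  invisible(rd(80 * ns))
  invisible(rd(8 * ns))                     # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  invisible(rd(80 * ns))
  spr <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  invisible(rd(32 * ns))
  if (length(unique(spr)) != 1L) {
    stop("EDF signals with differing sampling rates are unsupported",
         call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  samples <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[ch], size = 2, endian = "little")
      phys <- pmin_[ch] + (dig - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
      samples[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  ord <- match(eeg_channels(), labels)
  eeg_recording(samples[ord, , drop = FALSE], fs, eeg_channels(),
                state_label)
}

#' Read an EEG recording (CSV or EDF)
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"`, or `"edf"`.
#' @param ... passed to the format-specific reader.
#' @return an [eeg_recording()].
#' @export
read_eeg <- function(path, format = c("auto", "csv", "edf"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  switch(format,
         csv = read_eeg_csv(path, ...),
         edf = read_eeg_edf(path, ...))
}

TRIAL_COLUMNS <- c("participant", "emotion", "psycap_score", "psycap_group",
                   "RA", "RT1", "RS", "RT2",
                   "sleep", "smoke", "alcohol", "trainings", "lectures")

#' Write a behavioral trial table as CSV
#'
#' @param trials data.frame from [generate_trials()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing) > 0) {
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(trials[TRIAL_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read a behavioral trial table from CSV
#'
#' Expects the documented header
#' `participant,emotion,psycap_score,psycap_group,RA,RT1,RS,RT2,sleep,smoke,alcohol,trainings,lectures`.
#'
#' @param path CSV path.
#' @return data.frame with `emotion` and `psycap_group` as factors.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("trial CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$emotion <- factor(df$emotion, levels = EMOTIONS)
  df$psycap_group <- factor(df$psycap_group, levels = c("low", "high"))
  df
}
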