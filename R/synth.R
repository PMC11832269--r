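# Synthetic sleep-EEG generator.
#
# Emulates the shape of a serial-awakening dream-report dataset: 28 subjects,
# a 58-channel 10-10 montage referenced against linked mastoids (A1/A2),
# 400 Hz sampling, and a roughly 23/77 dream/dreamless class split.  The
# class effect is additive narrow-band oscillatory power on a configurable
# set of "informative" channels, superimposed on a 1/f-shaped background
# common to both classes, so that both a spatial-variance feature path (CSP)
# and a sub-band energy path (DWT) can detect it.

#' 58-channel 10-10 montage labels
#'
#' Standard extended 10-20 ("10-10") electrode labels used as the default
#' channel set of the synthetic generator, frontal to parieto-occipital.
#' Mastoids A1/A2 are not included; [synth_config()] appends them as
#' reference channels.
#'
#' @return Character vector of 58 electrode labels.
#' @export
montage_1010_58 <- function() {
  c(
    "Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8"
  )
}

#' Configuration for the synthetic EEG generator
#'
#' Bundles every knob of the generator into a validated object.  Defaults
#' mirror the recording conditions the pipeline targets: 28 subjects, a
#' 58-channel 10-10 montage plus two mastoid reference channels, 400 Hz raw
#' sampling, and a dream-class prior of 0.23.
#'
#' @param n_subjects Number of subjects.
#' @param channel_names Ordered channel labels. Must contain `A1`, `A2`
#'   (mastoids) and the frontal sites `Fpz`, `F3`, `F4`.
#' @param fs_raw Raw sampling rate in Hz (integer-valued).
#' @param epoch_len Epoch (report) duration in seconds.
#' @param epochs_per_subject Number of labeled epochs (reports) per subject.
#' @param class_prior Probability that an epoch is a dream report (label 1).
#' @param informative_channels Integer indices (1-based, into
#'   `channel_names`) of channels that carry the class effect.
#' @param effect_band Two-element numeric, Hz: band of the added dream-class
#'   oscillation. Must lie inside (0, fs_raw/2).
#' @param effect_size Amplitude of the class oscillation relative to
#'   `noise_sd` (0 disables the effect).
#' @param effect_expression Probability that an informative channel
#'   expresses the class oscillation in a given dream report (default
#'   0.85). Values below 1 model inter-report variability: no single
#'   channel shows the signature in every report, so channel combinations
#'   carry more information than any channel alone.
#' @param noise_sd Background noise scale in microvolts.
#' @param awake_fraction Probability that a report carries the
#'   awake-assumption flag.
#' @param subject_specific_channels If `TRUE` each subject receives its own
#'   random informative set (same size as `informative_channels`), producing
#'   a class effect that does not transfer across subjects. Useful for
#'   studying leave-one-subject-out generalization.
#' @param seed Master seed; per-subject streams are derived from it by a
#'   fixed offset so subjects are independent yet reproducible.
#'
#' @return An object of class `synth_config`.
#' @examples
#' cfg <- synth_config(n_subjects = 2, epochs_per_subject = 4)
#' cfg$n_channels
#' @export
synth_config <- function(n_subjects = 28,
                         channel_names = c(montage_1010_58(), "A1", "A2"),
                         fs_raw = 400,
                         epoch_len = 10,
                         epochs_per_subject = 8,
                         class_prior = 0.23,
                         informative_channels = match(c("Fpz", "Fp1", "Fp2"), channel_names),
                         effect_band = c(8, 12),
                         effect_size = 1,
                         effect_expression = 0.85,
                         noise_sd = 10,
                         awake_fraction = 0.343,
                         subject_specific_channels = FALSE,
                         seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects,
    n_channels = length(channel_names),
    channel_names = channel_names,
    fs_raw = fs_raw,
    epoch_len = epoch_len,
    epochs_per_subject = epochs_per_subject,
    class_prior = class_prior,
    informative_channels = as.integer(informative_channels),
    effect_band = effect_band,
    effect_size = effect_size,
    effect_expression = effect_expression,
    noise_sd = noise_sd,
    awake_fraction = awake_fraction,
    subject_specific_channels = isTRUE(subject_specific_channels),
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  for (f in c("n_subjects", "fs_raw", "epochs_per_subject")) {
    if (!is_count(cfg[[f]])) stopf("synth_config: '%s' must be a positive integer", f)
  }
  if (!(is.numeric(cfg$epoch_len) && cfg$epoch_len > 0)) {
    stopf("synth_config: 'epoch_len' must be positive")
  }
  if (abs(cfg$epoch_len * cfg$fs_raw - round(cfg$epoch_len * cfg$fs_raw)) > 1e-9) {
    stopf("synth_config: 'epoch_len' times 'fs_raw' must be an integer sample count")
  }
  if (!(cfg$class_prior > 0 && cfg$class_prior < 1)) {
    stopf("synth_config: 'class_prior' must lie strictly in (0, 1)")
  }
  if (!(cfg$awake_fraction >= 0 && cfg$awake_fraction <= 1)) {
    stopf("synth_config: 'awake_fraction' must lie in [0, 1]")
  }
  missing_names <- setdiff(c("A1", "A2", "Fpz", "F3", "F4"), cfg$channel_names)
  if (length(missing_names) > 0) {
    stopf("synth_config: 'channel_names' must include %s",
          paste(missing_names, collapse = ", "))
  }
  if (anyDuplicated(cfg$channel_names)) {
    stopf("synth_config: 'channel_names' contains duplicates")
  }
  ic <- cfg$informative_channels
  if (length(ic) > 0 && (anyNA(ic) || any(ic < 1 | ic > cfg$n_channels))) {
    stopf("synth_config: 'informative_channels' out of range 1..%d", cfg$n_channels)
  }
  mast <- match(c("A1", "A2"), cfg$channel_names)
  if (length(intersect(ic, mast)) > 0) {
    stopf("synth_config: 'informative_channels' must not include mastoids")
  }
  if (length(cfg$effect_band) != 2 || cfg$effect_band[1] <= 0 ||
      cfg$effect_band[1] >= cfg$effect_band[2] ||
      cfg$effect_band[2] >= cfg$fs_raw / 2) {
    stopf("synth_config: 'effect_band' must satisfy 0 < low < high < fs_raw/2")
  }
  if (!(is.numeric(cfg$effect_size) && cfg$effect_size >= 0)) {
    stopf("synth_config: 'effect_size' must be >= 0")
  }
  if (!(cfg$effect_expression > 0 && cfg$effect_expression <= 1)) {
    stopf("synth_config: 'effect_expression' must lie in (0, 1]")
  }
  if (!(is.numeric(cfg$noise_sd) && cfg$noise_sd > 0)) {
    stopf("synth_config: 'noise_sd' must be > 0")
  }
  invisible(cfg)
}

# 1/f-shaped ("pink") noise via FFT spectral shaping, unit variance.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)            # two-sided frequency index
  scale <- 1 / sqrt(pmax(f, 1))
  x <- Re(stats::fft(sp * scale, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s < .Machine$double.eps) return(rep(0, n)) else x / s
}

# One epoch of background EEG for one channel: pink noise plus delta/theta/
# alpha oscillations with random per-epoch frequency and phase.
background_channel <- function(n, fs, noise_sd) {
  t <- seq_len(n) / fs
  bands <- list(c(0.5, 4, 0.6), c(4, 8, 0.4), c(8, 12, 0.3))
  x <- 0.7 * pink_noise(n)
  for (b in bands) {
    f <- stats::runif(1, b[1], b[2])
    x <- x + b[3] * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
  }
  noise_sd * x
}

sleep_stages <- c("onset", "N1", "N2", "N3", "REM", "morning")
stage_probs <- c(0.20, 0.25, 0.30, 0.05, 0.15, 0.05)

#' Generate one subject's synthetic recording and labeled epochs
#'
#' Draws a continuous multichannel recording composed of consecutive labeled
#' epochs. Dream epochs (label 1) carry extra band-limited oscillatory power
#' on the informative channels; mastoid channels A1/A2 are low-amplitude so
#' mastoid re-referencing is testable but benign. The subject's RNG stream is
#' derived from the master seed and `subject_index`, so a fixed config is
#' fully deterministic.
#'
#' @param config A [synth_config()].
#' @param subject_id Subject identifier string.
#' @param subject_index 1-based index used to derive the subject RNG stream.
#' @return A list with `recording` (an `eeg_recording`) and `epochs` (a list
#'   of labeled epoch objects with fields `data`, `label`, `subject_id`,
#'   `report_id`, `stage`, `awake_assumed`, `start_s`).
#' @export
generate_subject_recording <- function(config, subject_id, subject_index = 1L) {
  validate_synth_config(config)
  if (!is_count(subject_index)) stopf("'subject_index' must be a positive integer")
  n_ep <- config$epochs_per_subject
  n_samp <- as.integer(round(config$epoch_len * config$fs_raw))
  n_ch <- config$n_channels
  mast <- match(c("A1", "A2"), config$channel_names)
  eeg_idx <- setdiff(seq_len(n_ch), mast)

  with_seed(config$seed + 7919L * as.integer(subject_index), {
    informative <- config$informative_channels
    if (config$subject_specific_channels && length(informative) > 0) {
      informative <- sample(eeg_idx, length(informative))
    }
    epochs <- vector("list", n_ep)
    data <- matrix(0, nrow = n_ch, ncol = n_samp * n_ep)
    t <- seq_len(n_samp) / config$fs_raw
    for (e in seq_len(n_ep)) {
      label <- stats::rbinom(1, 1, config$class_prior)
      awake <- stats::runif(1) < config$awake_fraction
      stage <- sample(sleep_stages, 1, prob = stage_probs)
      ep <- matrix(0, nrow = n_ch, ncol = n_samp)
      for (ch in seq_len(n_ch)) {
        if (ch %in% mast) {
          ep[ch, ] <- 0.05 * config$noise_sd * pink_noise(n_samp)
        } else {
          ep[ch, ] <- background_channel(n_samp, config$fs_raw, config$noise_sd)
        }
      }
      if (label == 1 && config$effect_size > 0 && length(informative) > 0) {
        for (ch in informative) {
          expressed <- stats::runif(1) < config$effect_expression
          f <- stats::runif(1, config$effect_band[1], config$effect_band[2])
          amp <- config$effect_size * config$noise_sd * stats::runif(1, 0.75, 1.25)
          if (!expressed) next
          ep[ch, ] <- ep[ch, ] + amp * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
        }
      }
      cols <- ((e - 1) * n_samp + 1):(e * n_samp)
      data[, cols] <- ep
      epochs[[e]] <- list(
        data = ep,
        fs = config$fs_raw,
        channel_names = config$channel_names,
        label = label,
        subject_id = subject_id,
        report_id = sprintf("%s_r%02d", subject_id, e),
        stage = stage,
        awake_assumed = awake,
        start_s = (e - 1) * config$epoch_len
      )
    }
    rec <- eeg_recording(data, config$fs_raw, config$channel_names,
                         subject_id, reference = "raw")
    list(recording = rec, epochs = epochs)
  })
}

#' Generate a full labeled synthetic dataset
#'
#' Runs [generate_subject_recording()] for every subject and pools the
#' labeled epochs.
#'
#' @param config A [synth_config()].
#' @param keep_recordings Keep the continuous per-subject recordings (needed
#'   by [export_fixture()]); drop them to save memory.
#' @return An object of class `eeg_dataset`: list with `epochs` (pooled
#'   labeled epochs), `recordings` (named list or `NULL`), and `config`.
#' @examples
#' ds <- generate_labeled_dataset(synth_config(n_subjects = 2,
#'                                             epochs_per_subject = 3,
#'                                             fs_raw = 100))
#' length(ds$epochs)
#' @export
generate_labeled_dataset <- function(config, keep_recordings = FALSE) {
  validate_synth_config(config)
  recordings <- list()
  epochs <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    out <- generate_subject_recording(config, sid, s)
    if (keep_recordings) recordings[[sid]] <- out$recording
    epochs <- c(epochs, out$epochs)
  }
  structure(
    list(epochs = epochs,
         recordings = if (keep_recordings) recordings else NULL,
         config = config),
    class = "eeg_dataset"
  )
}

#' @export
print.eeg_dataset <- function(x, ...) {
  labs <- vapply(x$epochs, `[[`, numeric(1), "label")
  cat(sprintf(
    "<eeg_dataset> %d epochs, %d subjects, %d channels @ %g Hz, dream fraction %.3f\n",
    length(x$epochs), x$config$n_subjects, x$config$n_channels,
    x$config$fs_raw, mean(labs)
  ))
  invisible(x)
}

#' Export a synthetic dataset as EDF files plus a JSON label sidecar
#'
#' Writes one EDF file per subject (channel labels preserved, physical range
#' fixed at +/-500 microvolt for a bit-exact quantization bound) and one JSON
#' sidecar per subject with the epoch labels, sleep stages, awake-assumption
#' flags and report identifiers. The fixture round-trips through
#' [read_recording()] up to EDF 16-bit quantization.
#'
#' @param dataset An `eeg_dataset` generated with `keep_recordings = TRUE`.
#' @param path Output directory (created if missing).
#' @return Invisibly, a data frame listing the files written.
#' @export
export_fixture <- function(dataset, path) {
  if (!inherits(dataset, "eeg_dataset")) stopf("'dataset' must be an eeg_dataset")
  if (length(dataset$epochs) == 0) stopf("dataset is empty; nothing to export")
  if (is.null(dataset$recordings)) {
    stopf("dataset lacks recordings; regenerate with keep_recordings = TRUE")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (sid in names(dataset$recordings)) {
    rec <- dataset$recordings[[sid]]
    eps <- Filter(function(e) identical(e$subject_id, sid), dataset$epochs)
    edf_path <- file.path(path, paste0(sid, ".edf"))
    json_path <- file.path(path, paste0(sid, ".json"))
    write_edf(rec, edf_path)
    sidecar <- list(
      subject_id = sid,
      fs = rec$fs,
      epochs = lapply(eps, function(e) {
        list(start_s = e$start_s,
             len_s = ncol(e$data) / rec$fs,
             label = e$label,
             stage = e$stage,
             awake_assumed = e$awake_assumed,
             report_id = e$report_id)
      })
    )
    jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA)
    files[[sid]] <- data.frame(subject_id = sid, edf = edf_path,
                               sidecar = json_path, stringsAsFactors = FALSE)
  }
  invisible(do.call(rbind, files))
}
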