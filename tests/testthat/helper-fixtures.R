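# Shared synthetic fixtures, built once per test session. All sizes are
# deliberately compact: generation happens at 100 Hz with short epochs so
# the full preprocessing chain (re-reference, band-pass, segmentation)
# still runs everywhere.

fixture_env <- new.env()

fx <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# compact 16-channel montage (plus mastoids) for strong-signal constructions
fx_ch16 <- function() {
  c("Fp1", "Fpz", "Fp2", "F3", "F4", "Fz", "C3", "Cz", "C4",
    "P3", "Pz", "P4", "O1", "Oz", "O2", "T7")
}

# tiny montage for exhaustive-oracle work: 6 EEG channels after re-reference
fx_ch6 <- function() c("Fp1", "Fpz", "Fp2", "F3", "F4", "Cz")

fx_knn <- function(seed = 1L) pipeline_config("csp", classifier_spec("KNN", k = 5, seed = seed))

# planted-signal set on the compact montage: 3 informative frontal channels
fx_signal16 <- function() fx("signal16", function() {
  cfg <- synth_config(n_subjects = 8, epochs_per_subject = 10, fs_raw = 100,
                      epoch_len = 10, effect_size = 3, class_prior = 0.23,
                      channel_names = c(fx_ch16(), "A1", "A2"),
                      informative_channels = 1:3, seed = 42)
  preprocess_dataset(generate_labeled_dataset(cfg), 100, c(0, 35), 2)
})

# balanced null set (no class effect) on the compact montage
fx_null16 <- function() fx("null16", function() {
  cfg <- synth_config(n_subjects = 6, epochs_per_subject = 8, fs_raw = 100,
                      epoch_len = 10, effect_size = 0, class_prior = 0.5,
                      channel_names = c(fx_ch16(), "A1", "A2"), seed = 9)
  preprocess_dataset(generate_labeled_dataset(cfg), 100, c(0, 35), 2)
})

# tiny planted set on the 6-channel montage (2 informative)
fx_signal6 <- function() fx("signal6", function() {
  cfg <- synth_config(n_subjects = 4, epochs_per_subject = 8, fs_raw = 100,
                      epoch_len = 6, effect_size = 3, class_prior = 0.4,
                      channel_names = c(fx_ch6(), "A1", "A2"),
                      informative_channels = 1:2, seed = 5)
  preprocess_dataset(generate_labeled_dataset(cfg), 100, c(0, 35), 2)
})

# hand-built segment set (no generator): deterministic array + metadata
fx_manual_segments <- function(n_seg = 40, n_ch = 4, n_samp = 64, seed = 3,
                               labels = NULL, subjects = NULL) {
  set.seed(seed)
  x <- array(rnorm(n_ch * n_samp * n_seg), dim = c(n_ch, n_samp, n_seg))
  labels <- labels %||% rep_len(c(0, 0, 0, 1), n_seg)
  subjects <- subjects %||% rep_len(paste0("S", 1:4), n_seg)
  meta <- data.frame(label = labels, subject_id = subjects,
                     report_id = paste0(subjects, "_r", seq_len(n_seg)),
                     stage = "N2", awake_assumed = FALSE,
                     stringsAsFactors = FALSE)
  segment_set(x, meta, fs = 32, segment_len = n_samp / 32,
              channel_names = paste0("ch", seq_len(n_ch)))
}

# per-channel band-power separation oracle: AUROC of spectral power in
# [low, high] Hz between the two classes, computed by brute force from the
# periodogram (independent of the package's feature paths)
fx_bandpower_auroc <- function(segments, low, high) {
  y <- segments$meta$label
  bp <- function(v, fs) {
    sp <- Mod(stats::fft(v))^2
    f <- (seq_along(v) - 1) * fs / length(v)
    sum(sp[f >= low & f <= high])
  }
  powers <- apply(segments$x, c(1, 3), bp, fs = segments$fs)
  apply(powers, 1, function(s) {
    r <- rank(s)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
}

# brute-force Pareto front oracle over an objective matrix (minimization)
fx_brute_front <- function(objs) {
  n <- nrow(objs)
  keep <- vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      j != i && all(objs[j, ] <= objs[i, ]) && any(objs[j, ] < objs[i, ])
    }, logical(1)))
  }, logical(1))
  which(keep)
}
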