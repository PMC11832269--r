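make_rec <- function(data, fs = 100, names = NULL) {
  names <- names %||% c(paste0("ch", seq_len(nrow(data) - 2)), "A1", "A2")
  eeg_recording(data, fs, names, "T01", reference = "raw")
}

test_that("mastoid re-referencing subtracts (A1+A2)/2 and drops mastoids", {
  # zero mastoids: channels unchanged
  d <- rbind(matrix(rnorm(300), 3), 0, 0)
  rec <- make_rec(d)
  out <- rereference_mastoids(rec)
  expect_equal(out$data, d[1:3, , drop = FALSE], ignore_attr = TRUE)
  expect_identical(out$reference, "mastoid-average")
  expect_false(any(c("A1", "A2") %in% out$channel_names))

  # constant arithmetic: 10 - (2+4)/2 = 7
  d2 <- rbind(matrix(10, 1, 50), matrix(2, 1, 50), matrix(4, 1, 50))
  out2 <- rereference_mastoids(make_rec(d2, names = c("Cz", "A1", "A2")))
  expect_equal(unique(as.vector(out2$data)), 7)

  # algebraic inverse: result + (A1+A2)/2 recovers the original exactly
  d3 <- rbind(matrix(rnorm(400), 4), matrix(rnorm(200), 2))
  rec3 <- make_rec(d3)
  out3 <- rereference_mastoids(rec3)
  ref <- colMeans(d3[5:6, ])
  back <- out3$data + matrix(ref, 4, 100, byrow = TRUE)
  expect_equal(mean(back - d3[1:4, ]), 0)

  expect_error(rereference_mastoids(out3), "re-referenced")
  expect_error(rereference_mastoids(make_rec(d2, names = c("Cz", "A1", "X"))), "A1")
})

test_that("resampling halves counts, preserves tones, and is identity at fs", {
  t <- seq_len(4000) / 400
  d <- rbind(sin(2 * pi * 10 * t), cos(2 * pi * 3 * t), 0, 0)
  rec <- make_rec(d, fs = 400, names = c("c1", "c2", "A1", "A2"))
  out <- resample_recording(rec, 200)
  expect_equal(out$fs, 200)
  expect_equal(ncol(out$data), 2000)

  # identity when target equals current rate
  same <- resample_recording(rec, 400)
  expect_lt(max(abs(same$data - rec$data)), 1e-9)

  # dominant periodogram peak of a 10 Hz tone survives 2:1 decimation
  sp <- Mod(stats::fft(out$data[1, ]))^2
  f <- (seq_len(2000) - 1) * 200 / 2000
  half <- f <= 100
  expect_lt(abs(f[half][which.max(sp[half][-1]) + 1] - 10), 0.5)

  expect_error(resample_recording(rec, -5), "target_fs")
  expect_error(resample_recording(rec, 500), "exceed")
})

test_that("zero-phase band-pass attenuates stop band and passes pass band", {
  t <- seq_len(2000) / 200
  tone <- function(f) sin(2 * pi * f * t)
  rec <- make_rec(rbind(tone(50), tone(10), 0, 0), fs = 200,
                  names = c("c1", "c2", "c3", "A1"))
  out <- bandpass_filter(rec, 0, 35)
  rms <- function(v) sqrt(mean(v^2))
  mid <- 500:1500  # interior, away from filter edge transients
  expect_lte(rms(out$data[1, mid]), 0.01 * rms(rec$data[1, mid]))
  expect_gte(rms(out$data[2, mid]), 0.95 * rms(rec$data[2, mid]))
  expect_equal(out$data[3, ], rep(0, 2000))
  expect_error(bandpass_filter(rec, 30, 20), "invalid band")
  expect_error(bandpass_filter(rec, 0, 150), "invalid band")
})

test_that("segmentation produces non-overlapping inherited-label segments", {
  mk_epoch <- function(len_s, label, fs = 200, report = "r1") {
    list(data = matrix(rnorm(2 * len_s * fs), 2), fs = fs, label = label,
         subject_id = "S01", report_id = report, stage = "REM",
         awake_assumed = FALSE, channel_names = c("c1", "c2"))
  }
  segs <- segment_epochs(list(mk_epoch(30, 1)), 2)
  expect_equal(n_segments(segs), 15)
  expect_equal(dim(segs$x)[2], 400)
  expect_true(all(segs$meta$label == 1))

  # 5-s epoch with 2-s segments: 2 segments, 1 s discarded
  segs2 <- segment_epochs(list(mk_epoch(5, 0)), 2)
  expect_equal(n_segments(segs2), 2)

  # sample conservation up to discarded remainders
  eps <- list(mk_epoch(5, 0, report = "r1"), mk_epoch(7, 1, report = "r2"))
  segs3 <- segment_epochs(eps, 2)
  total_in <- sum(vapply(eps, function(e) ncol(e$data), numeric(1)))
  remainders <- sum(vapply(eps, function(e) ncol(e$data) %% 400, numeric(1)))
  expect_equal(n_segments(segs3) * 400, total_in - remainders)

  # epochs shorter than one segment are skipped with a warning
  expect_warning(out <- segment_epochs(list(mk_epoch(30, 1), mk_epoch(1, 0))), "skipped")
  expect_equal(n_segments(out), 15)
  expect_error(suppressWarnings(segment_epochs(list(mk_epoch(1, 0)), 2)), "shorter")
})

test_that("stratified folds partition the data and preserve class ratio", {
  segs <- fx_manual_segments(n_seg = 100, labels = rep_len(c(rep(0, 77), rep(1, 23)), 100))
  plan <- make_cv_splits(segs, "stratified-k-fold", k = 10, seed = 4)
  all_test <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  expect_identical(all_test, 1:100)
  for (fold in plan$folds) {
    expect_length(intersect(fold$train, fold$test), 0)
    n_dream <- sum(segs$meta$label[fold$test] == 1)
    expect_gte(n_dream, 2)
    expect_lte(n_dream, 3)
  }
  # determinism
  plan2 <- make_cv_splits(segs, "stratified-k-fold", k = 10, seed = 4)
  expect_identical(plan, plan2)
  expect_error(make_cv_splits(fx_manual_segments(labels = rep(0, 40))), "both classes")
})

test_that("LOSO yields one fold per subject, each testing exactly that subject", {
  segs <- fx_manual_segments(n_seg = 60, subjects = rep(paste0("S", 1:6), each = 10))
  plan <- make_cv_splits(segs, "loso")
  expect_length(plan$folds, 6)
  for (fold in plan$folds) {
    expect_length(unique(segs$meta$subject_id[fold$test]), 1)
    expect_equal(sort(c(fold$train, fold$test)), 1:60)
  }
})

test_that("by-report grouping keeps every report on one side of each fold", {
  segs <- fx_manual_segments(n_seg = 80,
                             labels = rep(rep_len(c(0, 0, 0, 1), 20), each = 4),
                             subjects = rep(paste0("S", 1:4), each = 20))
  segs$meta$report_id <- rep(paste0("r", 1:20), each = 4)
  plan <- make_cv_splits(segs, "stratified-k-fold", k = 5, seed = 2,
                         grouping = "by-report")
  for (fold in plan$folds) {
    test_reports <- unique(segs$meta$report_id[fold$test])
    train_reports <- unique(segs$meta$report_id[fold$train])
    expect_length(intersect(test_reports, train_reports), 0)
  }
})

test_that("balancing downsamples only the majority class", {
  segs <- fx_manual_segments(n_seg = 130, labels = c(rep(0, 100), rep(1, 30)))
  bal <- balance_subset(segs, seed = 1)
  expect_equal(as.vector(table(bal$meta$label)), c(30, 30))

  already <- fx_manual_segments(n_seg = 60, labels = rep(c(0, 1), 30))
  expect_equal(sort(balance_subset(already, 1)$meta$report_id),
               sort(already$meta$report_id))

  # different seeds redraw the majority subset but never touch the minority
  picks <- lapply(1:5, function(s) balance_subset(segs, seed = s)$meta$report_id)
  minority <- segs$meta$report_id[segs$meta$label == 1]
  for (p in picks) expect_true(all(minority %in% p))
  expect_gt(length(unique(lapply(picks, sort))), 1)
  expect_error(balance_subset(fx_manual_segments(labels = rep(1, 40))), "both classes")
})
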