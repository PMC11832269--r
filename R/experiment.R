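# Experiment orchestration: subset filters (awake-assumption and
# balancing), the random-channel baseline, and a config-driven runner that
# executes a configured pipeline end to end and writes a report bundle.

#' Filter a segment set by awake assumption and balance
#'
#' `awake = "W"` keeps only instances carrying the awake-assumption flag,
#' `"nW"` keeps only those without it, `"all"` keeps everything. With
#' `balanced = TRUE` the majority class is randomly downsampled to the
#' minority size afterwards (the minority class is never altered).
#'
#' @param segments A `segment_set`.
#' @param awake `"all"`, `"W"`, or `"nW"`.
#' @param balanced Logical.
#' @param seed Seed for the balancing draw.
#' @return A filtered `segment_set`.
#' @export
filter_subset <- function(segments, awake = c("all", "W", "nW"),
                          balanced = FALSE, seed = 1L) {
  awake <- match.arg(awake)
  keep <- switch(awake,
                 all = seq_len(n_segments(segments)),
                 W = which(segments$meta$awake_assumed),
                 nW = which(!segments$meta$awake_assumed))
  if (length(keep) == 0) stopf("subset '%s' is empty", awake)
  out <- subset_segments(segments, keep)
  if (balanced) out <- balance_subset(out, seed = seed)
  out
}

#' Random channel-subset baseline
#'
#' Draws `k` channels uniformly without replacement, evaluates the full
#' pipeline by cross-validation, and averages over `reps` independent
#' draws. Serves as the chance baseline against which permutation- and
#' NSGA-selected subsets are judged.
#'
#' @param segments A `segment_set`.
#' @param k Number of channels per draw (1..C).
#' @param config A [pipeline_config()].
#' @param reps Number of random draws (default 10).
#' @param folds CV folds per draw (default 10).
#' @param seed Seed for the draws and folds.
#' @return An `evaluation_report` whose rows are the per-rep mean metrics;
#'   the drawn subsets are attached as `$subsets`.
#' @export
random_subset_experiment <- function(segments, k, config, reps = 10,
                                     folds = 10, seed = 1L) {
  n_ch <- dim(segments$x)[1]
  if (!is_count(k) || k > n_ch) stopf("invalid k = %s (1..%d)", k, n_ch)
  subsets <- with_seed(seed, lapply(seq_len(reps), function(r) sample(n_ch, k)))
  rows <- list()
  for (r in seq_len(reps)) {
    sub <- restrict_channels(segments, subsets[[r]])
    plan <- make_cv_splits(sub, "stratified-k-fold", k = folds,
                           seed = seed + r)
    rep_ <- crossval_evaluate(sub, config, plan)
    rows[[r]] <- rep_$mean
  }
  out <- make_report(rows, NULL,
                     config_echo = list(k = k, reps = reps, seed = seed,
                                        feature = config$feature,
                                        classifier = config$classifier$name))
  out$subsets <- subsets
  out
}

#' Run a configured experiment end to end
#'
#' Executes generation/loading, preprocessing, subset filtering, evaluation
#' and (optionally) channel selection from a single configuration list, and
#' writes `report.json`, `metrics.csv`, `confusion.csv` and `log.txt` to
#' `out_dir`. Identical configurations produce identical reports.
#'
#' Configuration fields (all optional unless noted):
#' \describe{
#'   \item{data}{Either a [synth_config()] (required) or a list
#'     `list(fixture_dir = ...)` pointing at an [export_fixture()] bundle.}
#'   \item{preprocess}{`target_fs` (default 200), `band` (default c(0, 35)),
#'     `segment_len` (default 2).}
#'   \item{feature}{`"csp"` or `"dwt"`.}
#'   \item{classifier}{Name for [classifier_spec()] (default "KNN").}
#'   \item{evaluation}{`"cv10"`, `"loso"`, or `"single-split"`.}
#'   \item{subset}{`awake` in all/W/nW; `balanced` logical.}
#'   \item{chansel}{`method` in none/permutation/nsga/random-k; `k` for
#'     random-k; `nsga` options forwarded to [nsga_config()].}
#'   \item{seed}{Master seed (default 1).}
#' }
#'
#' @param config Configuration list (or path to a YAML file with the same
#'   structure, requires the yaml package).
#' @param out_dir Output directory.
#' @return Invisibly, the report list.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_ <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }
  seed <- config$seed %||% 1L
  stage <- "data"
  report <- tryCatch({
    segments <- local({
      log_("stage %s: loading data (seed %d)", stage, seed)
      pp <- config$preprocess %||% list()
      target_fs <- pp$target_fs %||% 200
      band <- pp$band %||% c(0, 35)
      seg_len <- pp$segment_len %||% 2
      if (inherits(config$data, "synth_config")) {
        ds <- generate_labeled_dataset(config$data)
        preprocess_dataset(ds, target_fs, band, seg_len)
      } else if (!is.null(config$data$fixture_dir)) {
        edfs <- sort(list.files(config$data$fixture_dir, "\\.edf$",
                                full.names = TRUE))
        if (length(edfs) == 0) stopf("no EDF files in fixture_dir")
        epochs <- list()
        for (f in edfs) {
          side <- sub("\\.edf$", ".json", f)
          epochs <- c(epochs, read_recording(f, side)$epochs)
        }
        preprocess_dataset(epochs, target_fs, band, seg_len)
      } else {
        stopf("config$data must be a synth_config or list(fixture_dir = ...)")
      }
    })
    stage <- "subset"
    sub <- config$subset %||% list()
    segments <- filter_subset(segments, sub$awake %||% "all",
                              isTRUE(sub$balanced), seed = seed)
    log_("stage subset: %d segments (awake=%s, balanced=%s)",
         n_segments(segments), sub$awake %||% "all", isTRUE(sub$balanced))

    stage <- "pipeline"
    pconf <- pipeline_config(
      feature = config$feature %||% "csp",
      classifier = classifier_spec(config$classifier %||% "KNN", seed = seed)
    )

    stage <- "evaluation"
    design <- config$evaluation %||% "cv10"
    evaluation <- switch(design,
      cv10 = crossval_evaluate(segments, pconf,
                               make_cv_splits(segments, "stratified-k-fold",
                                              k = 10, seed = seed)),
      loso = loso_evaluate(segments, pconf),
      `single-split` = single_split_evaluate(segments, pconf, seed = seed),
      stopf("unknown evaluation design '%s'", design))
    log_("stage evaluation: %s done", design)

    stage <- "chansel"
    cs <- config$chansel %||% list(method = "none")
    chansel <- switch(cs$method %||% "none",
      none = NULL,
      permutation = channel_importance(segments, pconf,
                                       folds = cs$folds %||% 10, seed = seed),
      nsga = run_nsga(nsga_config(seed = seed,
                                  population_size = cs$pop %||% 15,
                                  max_generations = cs$gens %||% 200),
                      segments, pconf, split_seed = seed),
      `random-k` = {
        if (is.null(cs$k)) stopf("chansel method random-k requires k")
        random_subset_experiment(segments, cs$k, pconf,
                                 reps = cs$reps %||% 10, seed = seed)
      },
      stopf("unknown channel-selection method '%s'", cs$method))
    if (!is.null(chansel)) log_("stage chansel: %s done", cs$method)

    list(config = config, seed = seed, evaluation = evaluation,
         chansel = chansel)
  }, error = function(e) {
    stop(sprintf("experiment failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  # serialize the bundle
  ev <- report$evaluation
  metrics_df <- if (inherits(ev, "evaluation_report")) {
    cbind(fold = seq_len(nrow(ev$per_fold)), as.data.frame(ev$per_fold))
  } else if (!is.null(ev$per_subject)) {
    ev$per_subject
  } else {
    as.data.frame(t(metrics_to_row(ev$metrics)))
  }
  utils::write.csv(metrics_df, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  conf <- if (inherits(ev, "evaluation_report") && length(ev$confusion) > 0) {
    Reduce(`+`, ev$confusion)
  } else if (!is.null(ev$confusion)) ev$confusion else NULL
  if (!is.null(conf)) {
    utils::write.csv(as.data.frame(conf), file.path(out_dir, "confusion.csv"))
  }
  json_report <- list(
    seed = report$seed,
    evaluation = if (inherits(ev, "evaluation_report")) {
      list(mean = as.list(ev$mean), sd = as.list(ev$sd))
    } else if (!is.null(ev$overall)) {
      list(mean = as.list(ev$overall$mean), sd = as.list(ev$overall$sd))
    } else {
      list(metrics = unclass(ev$metrics))
    },
    config_echo = list(feature = report$config$feature %||% "csp",
                       classifier = report$config$classifier %||% "KNN",
                       evaluation = report$config$evaluation %||% "cv10",
                       seed = report$seed)
  )
  jsonlite::write_json(json_report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(report)
}
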