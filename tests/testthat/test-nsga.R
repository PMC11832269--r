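test_that("dominance follows the strict-in-one definition", {
  expect_true(dominates(c(2, -0.90), c(3, -0.90)))
  expect_false(dominates(c(2, -0.90), c(3, -0.95)))
  expect_false(dominates(c(2, -0.9), c(2, -0.9)))
  expect_true(dominates(c(1, 1, 1), c(1, 1, 2)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "length")
})

test_that("non-dominated sorting matches the brute-force oracle", {
  set.seed(12)
  for (i in 1:5) {
    objs <- matrix(sample(1:5, 60, replace = TRUE), 20, 3)
    fronts <- dreamsift:::nondominated_sort(objs)
    expect_setequal(fronts[[1]], fx_brute_front(objs))
    expect_setequal(unlist(fronts), 1:20)
  }
})

test_that("chromosome repair fixes only all-zero masks, uniformly", {
  m <- rep(0L, 58)
  set.seed(13)
  fixed <- repair_chromosome(m)
  expect_equal(sum(fixed), 1)
  nz <- c(1L, rep(0L, 57))
  expect_identical(repair_chromosome(nz), nz)
  set.seed(14)
  picks <- replicate(1000, which(repair_chromosome(rep(0L, 8)) == 1))
  expect_gt(chisq.test(table(factor(picks, levels = 1:8)))$p.value, 0.01)
})

test_that("chromosome evaluation restricts channels and is memoized", {
  segs <- fx_signal6()
  pc <- fx_knn()
  cache <- new.env(parent = emptyenv())
  full <- rep(1L, 6)
  ev <- evaluate_chromosome(full, segs, pc, split_seed = 2, cache = cache)
  expect_equal(unname(ev$objectives[1]), 6)
  ref <- single_split_evaluate(segs, pc, seed = 2)
  expect_equal(ev$metrics$accuracy, ref$metrics$accuracy)
  expect_equal(unname(ev$objectives[-1]),
               -unname(unlist(ref$metrics)[c("accuracy", "fscore", "precision",
                                             "recall", "auroc")]))
  # second call: cache hit, no new evaluation
  n_evals <- cache$evals
  ev2 <- evaluate_chromosome(full, segs, pc, split_seed = 2, cache = cache)
  expect_identical(ev, ev2)
  expect_equal(cache$evals, n_evals)
  expect_equal(cache$hits, 1L)
  expect_error(evaluate_chromosome(rep(0L, 6), segs, pc), "all-zero")

  # planted-subset ordering: the informative pair beats a noise pair
  planted <- evaluate_chromosome(c(1L, 1L, 0L, 0L, 0L, 0L), segs, pc, 2)
  noise <- evaluate_chromosome(c(0L, 0L, 0L, 0L, 1L, 1L), segs, pc, 2)
  expect_gt(planted$metrics$auroc, noise$metrics$auroc)
})

test_that("the returned front is valid, deterministic, and elitist", {
  segs <- fx_signal6()
  pc <- fx_knn()
  cfg <- nsga_config(population_size = 8, max_generations = 30,
                     tolerance_period = 10, seed = 6)
  res <- run_nsga(cfg, segs, pc, split_seed = 2)
  objs <- do.call(rbind, lapply(res$front, `[[`, "objectives"))
  # no dominated pairs inside the returned front (brute-force check)
  expect_setequal(fx_brute_front(objs), seq_len(nrow(objs)))
  # determinism
  res2 <- run_nsga(cfg, segs, pc, split_seed = 2)
  expect_identical(lapply(res$front, `[[`, "mask"),
                   lapply(res2$front, `[[`, "mask"))
  # elitism: per-objective bests never worsen over generations
  h <- res$history
  expect_true(all(diff(h$best_channels) <= 0))
  expect_true(all(diff(h$best_accuracy) >= 0))
  expect_true(all(diff(h$best_auroc) >= 0))
})

test_that("the search recovers the true front on an exhaustive toy", {
  segs <- fx_signal6()
  pc <- fx_knn()
  cache <- new.env(parent = emptyenv())
  masks <- lapply(1:63, function(i) as.integer(intToBits(i)[1:6]))
  objs <- do.call(rbind, lapply(masks, function(m) {
    evaluate_chromosome(m, segs, pc, split_seed = 2, cache = cache)$objectives
  }))
  true_front <- masks[fx_brute_front(objs)]
  res <- run_nsga(nsga_config(population_size = 10, max_generations = 40, seed = 1),
                  segs, pc, split_seed = 2)
  true_keys <- vapply(true_front, paste, "", collapse = "")
  got_keys <- vapply(res$front, function(s) paste(s$mask, collapse = ""), "")
  expect_true(all(got_keys %in% true_keys))
})

test_that("pareto_curve reports per-count bests and gaps", {
  front <- list(
    list(mask = c(1L, 0L, 0L), metrics = list(accuracy = 0.7, fscore = 0.6,
                                              precision = 0.6, recall = 0.6, auroc = 0.7)),
    list(mask = c(1L, 0L, 1L), metrics = list(accuracy = 0.9, fscore = 0.8,
                                              precision = 0.8, recall = 0.8, auroc = 0.9)),
    list(mask = c(0L, 0L, 1L), metrics = list(accuracy = 0.75, fscore = 0.6,
                                              precision = 0.6, recall = 0.6, auroc = 0.72))
  )
  tab <- pareto_curve(front)
  expect_equal(tab$n_channels, c(1, 2))  # count 3 absent: a gap, not a row
  expect_equal(tab$accuracy, c(0.75, 0.9))
  single <- pareto_curve(front[2])
  expect_equal(nrow(single), 1)
  expect_error(pareto_curve(list()), "empty")
})
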