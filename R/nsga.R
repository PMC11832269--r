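# Six-objective NSGA-II channel-subset search. A binary chromosome marks
# which channels enter the pipeline; the objectives, all minimized, are the
# active-channel count and the negated five metrics of a seeded 70/30
# split evaluation. Standard binary-encoding operators (uniform crossover,
# per-gene bit-flip mutation), non-dominated sorting with crowding
# distance, and an elitist merge of parents and offspring.

#' NSGA-II configuration
#'
#' @param population_size Chromosomes per generation (default 15).
#' @param max_generations Hard generation cap (default 200).
#' @param tolerance Objective-space tolerance: the search stops when the
#'   normalized change of the non-dominated set's objective bounding box
#'   between checks falls below this (default 0.001).
#' @param tolerance_period Generations between tolerance checks (default 10).
#' @param crossover_prob Per-pair uniform crossover probability (default 0.9).
#' @param mutation_prob Per-gene bit-flip probability (default 1/C).
#' @param seed Seed for the whole run.
#' @return An `nsga_config`.
#' @export
nsga_config <- function(population_size = 15, max_generations = 200,
                        tolerance = 0.001, tolerance_period = 10,
                        crossover_prob = 0.9, mutation_prob = NULL,
                        seed = 1L) {
  if (!is_count(population_size) || population_size < 4) {
    stopf("population_size must be an integer >= 4")
  }
  if (!(tolerance > 0)) stopf("tolerance must be > 0")
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 tolerance = tolerance,
                 tolerance_period = as.integer(tolerance_period),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 objective_count = 6L,
                 seed = as.integer(seed)),
            class = "nsga_config")
}

#' Pareto dominance (minimization)
#'
#' `a` dominates `b` iff `a <= b` in every component and `a < b` in at
#' least one.
#'
#' @param a,b Numeric objective vectors of equal length.
#' @return Logical.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) stopf("objective vectors differ in length")
  all(a <= b) && any(a < b)
}

#' Repair a degenerate chromosome
#'
#' An all-zero mask (no channels selected) is repaired by setting one
#' uniformly random gene; any non-zero mask is returned unchanged. Uses the
#' current RNG stream.
#'
#' @param mask Binary integer vector.
#' @return A valid mask with at least one active gene.
#' @export
repair_chromosome <- function(mask) {
  if (sum(mask) == 0) mask[sample(length(mask), 1)] <- 1L
  mask
}

#' Evaluate one channel-subset chromosome
#'
#' Restricts the data to the active channels, runs a seeded stratified
#' 70/30 split through the full pipeline, and returns the objective vector
#' `(active count, -accuracy, -fscore, -precision, -recall, -auroc)` along
#' with the raw metrics. Results are memoized by mask bit-pattern when a
#' cache environment is supplied.
#'
#' @param mask Binary vector over channels, at least one gene active.
#' @param segments A `segment_set`.
#' @param pipeline A [pipeline_config()].
#' @param split_seed Seed of the 70/30 split (held fixed across masks so
#'   subsets compete on identical data).
#' @param cache Optional environment for memoization (tracks `evals` and
#'   `hits` counters).
#' @return List with `objectives` (length 6) and `metrics` (a `metric_set`).
#' @export
evaluate_chromosome <- function(mask, segments, pipeline, split_seed = 1L,
                                cache = NULL) {
  if (sum(mask) == 0) stopf("all-zero mask reached evaluation; repair first")
  key <- paste(mask, collapse = "")
  if (!is.null(cache) && !is.null(cache$store[[key]])) {
    cache$hits <- (cache$hits %||% 0L) + 1L
    return(cache$store[[key]])
  }
  sub <- restrict_channels(segments, which(mask == 1))
  res <- single_split_evaluate(sub, pipeline, train_frac = 0.7, seed = split_seed)
  m <- res$metrics
  out <- list(
    objectives = c(channels = sum(mask), acc = -m$accuracy, fscore = -m$fscore,
                   precision = -m$precision, recall = -m$recall,
                   auroc = -(m$auroc %||% 0)),
    metrics = m
  )
  if (!is.null(cache)) {
    if (is.null(cache$store)) cache$store <- list()
    cache$store[[key]] <- out
    cache$evals <- (cache$evals %||% 0L) + 1L
  }
  out
}

# Fast non-dominated sorting over an objective matrix (rows = solutions).
nondominated_sort <- function(objs) {
  n <- nrow(objs)
  dom_count <- integer(n)
  dominated_by <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(objs[i, ], objs[j, ])) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (dominates(objs[j, ], objs[i, ])) {
        dom_count[i] <- dom_count[i] + 1L
      }
    }
  }
  fronts <- list()
  current <- which(dom_count == 0L)
  while (length(current) > 0) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated_by[[i]]) {
        dom_count[j] <- dom_count[j] - 1L
        if (dom_count[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- nxt
  }
  fronts
}

# Crowding distance within one front.
crowding_distance <- function(objs) {
  n <- nrow(objs)
  if (n <= 2) return(rep(Inf, n))
  dist <- numeric(n)
  for (m in seq_len(ncol(objs))) {
    ord <- order(objs[, m])
    rng <- objs[ord[n], m] - objs[ord[1], m]
    dist[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      for (i in 2:(n - 1)) {
        dist[ord[i]] <- dist[ord[i]] + (objs[ord[i + 1], m] - objs[ord[i - 1], m]) / rng
      }
    }
  }
  dist
}

# Bounding box of an objective matrix (per-objective min and max).
objective_box <- function(objs) {
  rbind(apply(objs, 2, min), apply(objs, 2, max))
}

#' Run the NSGA-II channel-subset search
#'
#' Evolves a population of binary channel masks toward the Pareto front of
#' (few channels, high metrics). Selection is a binary tournament on
#' (non-domination rank, crowding distance); each generation merges parents
#' and offspring elitistically. The search stops when the non-dominated
#' set's objective bounding box changes by less than `tolerance` (relative,
#' checked every `tolerance_period` generations) or at `max_generations`.
#'
#' @param config An [nsga_config()].
#' @param segments A `segment_set`.
#' @param pipeline A [pipeline_config()].
#' @param split_seed Seed of the per-chromosome 70/30 evaluation split.
#' @return List with `front` (list of solutions: `mask`, `channels`,
#'   `objectives`, `metrics`), `history` (per-generation data frame),
#'   `generations` run, and `cache` statistics.
#' @export
run_nsga <- function(config, segments, pipeline, split_seed = 1L) {
  if (!inherits(config, "nsga_config")) stopf("'config' must be an nsga_config")
  n_ch <- dim(segments$x)[1]
  n_pop <- config$population_size
  p_mut <- config$mutation_prob %||% (1 / n_ch)
  cache <- new.env(parent = emptyenv())

  with_seed(config$seed, {
    pop <- lapply(seq_len(n_pop), function(i) {
      repair_chromosome(as.integer(stats::runif(n_ch) < 0.5))
    })
    evals <- lapply(pop, evaluate_chromosome, segments = segments,
                    pipeline = pipeline, split_seed = split_seed, cache = cache)
    objs <- do.call(rbind, lapply(evals, `[[`, "objectives"))
    history <- list()
    prev_box <- NULL
    gen_done <- 0L

    for (gen in seq_len(config$max_generations)) {
      fronts <- nondominated_sort(objs)
      rank <- integer(n_pop)
      crowd <- numeric(n_pop)
      for (fi in seq_along(fronts)) {
        rank[fronts[[fi]]] <- fi
        crowd[fronts[[fi]]] <- crowding_distance(objs[fronts[[fi]], , drop = FALSE])
      }
      tournament <- function() {
        cand <- sample(n_pop, 2)
        a <- cand[1]; b <- cand[2]
        if (rank[a] < rank[b]) a
        else if (rank[b] < rank[a]) b
        else if (crowd[a] >= crowd[b]) a else b
      }
      offspring <- vector("list", n_pop)
      i <- 1L
      while (i <= n_pop) {
        p1 <- pop[[tournament()]]
        p2 <- pop[[tournament()]]
        if (stats::runif(1) < config$crossover_prob) {
          swap <- stats::runif(n_ch) < 0.5
          c1 <- ifelse(swap, p2, p1)
          c2 <- ifelse(swap, p1, p2)
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          if (i > n_pop) break
          flips <- stats::runif(n_ch) < p_mut
          child[flips] <- 1L - child[flips]
          offspring[[i]] <- repair_chromosome(as.integer(child))
          i <- i + 1L
        }
      }
      off_evals <- lapply(offspring, evaluate_chromosome, segments = segments,
                          pipeline = pipeline, split_seed = split_seed,
                          cache = cache)
      all_pop <- c(pop, offspring)
      all_evals <- c(evals, off_evals)
      all_objs <- rbind(objs, do.call(rbind, lapply(off_evals, `[[`, "objectives")))
      merged_fronts <- nondominated_sort(all_objs)
      keep <- integer(0)
      for (fr in merged_fronts) {
        if (length(keep) + length(fr) <= n_pop) {
          keep <- c(keep, fr)
        } else {
          cd <- crowding_distance(all_objs[fr, , drop = FALSE])
          keep <- c(keep, fr[order(-cd)][seq_len(n_pop - length(keep))])
          break
        }
      }
      pop <- all_pop[keep]
      evals <- all_evals[keep]
      objs <- all_objs[keep, , drop = FALSE]
      gen_done <- gen

      nd <- nondominated_sort(objs)[[1]]
      history[[gen]] <- data.frame(
        generation = gen, front_size = length(nd),
        best_channels = min(objs[, 1]),
        best_accuracy = -min(objs[, 2]), best_auroc = -min(objs[, 6]))

      if (gen %% config$tolerance_period == 0) {
        box <- objective_box(objs[nd, , drop = FALSE])
        if (!is.null(prev_box)) {
          rng <- pmax(prev_box[2, ] - prev_box[1, ], 1e-12)
          change <- max(abs(box - prev_box) / rep(rng, each = 2))
          if (change < config$tolerance) break
        }
        prev_box <- box
      }
    }

    nd <- nondominated_sort(objs)[[1]]
    keys <- vapply(pop[nd], paste, "", collapse = "")
    nd <- nd[!duplicated(keys)]
    front <- lapply(nd, function(i) {
      list(mask = pop[[i]],
           channels = segments$channel_names[pop[[i]] == 1],
           objectives = objs[i, ],
           metrics = evals[[i]]$metrics)
    })
    list(front = front,
         history = do.call(rbind, history),
         generations = gen_done,
         cache = list(evals = cache$evals %||% 0L, hits = cache$hits %||% 0L))
  })
}

#' Per-channel-count best metrics along a Pareto front
#'
#' For every channel count present in the front, reports the best value of
#' each metric among its members; counts absent from the front are gaps
#' (not rows).
#'
#' @param front List of Pareto solutions as returned by [run_nsga()].
#' @return Data frame: `n_channels` plus the best of each metric.
#' @export
pareto_curve <- function(front) {
  if (length(front) == 0) stopf("empty front")
  counts <- vapply(front, function(s) sum(s$mask), numeric(1))
  rows <- lapply(sort(unique(counts)), function(k) {
    members <- front[counts == k]
    best <- vapply(metric_names, function(m) {
      max(vapply(members, function(s) s$metrics[[m]] %||% NA_real_, numeric(1)),
          na.rm = TRUE)
    }, numeric(1))
    c(n_channels = k, best)
  })
  as.data.frame(do.call(rbind, rows))
}
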