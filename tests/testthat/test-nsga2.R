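test_that("dominates follows strict Pareto semantics", {
  expect_true(dominates(0.8, 10, 0.7, 20))
  expect_false(dominates(0.8, 10, 0.9, 5))
  expect_true(dominates(0.9, 5, 0.8, 10))
  expect_false(dominates(0.8, 10, 0.8, 10))   # equal: neither dominates
  expect_false(dominates(0.8, 10, 0.8, 10))
  expect_true(dominates(0.8, 9, 0.8, 10))     # equal kappa, smaller set
  expect_error(dominates(NA, 1, 0.5, 2), "evaluated")
})

test_that("non_dominated_sort matches the peeling oracle", {
  # single individual and an all-non-dominated staircase
  expect_equal(non_dominated_sort(0.5, 3), list(1L))
  k <- c(0.5, 0.6, 0.7, 0.8); n <- c(1, 2, 3, 4)
  expect_equal(non_dominated_sort(k, n), list(1:4))

  # 8 hand-placed points
  k8 <- c(0.9, 0.8, 0.8, 0.7, 0.6, 0.9, 0.5, 0.4)
  n8 <- c(10, 5, 12, 4, 4, 20, 2, 2)
  expect_equal(lapply(non_dominated_sort(k8, n8), sort),
               peel_fronts(k8, n8))

  # random-population property (fixed seed)
  set.seed(13)
  for (rep in 1:30) {
    m <- sample(2:30, 1)
    kk <- round(runif(m), 2)  # coarse grid provokes objective ties
    nn <- sample(1:12, m, replace = TRUE)
    fronts <- non_dominated_sort(kk, nn)
    expect_equal(lapply(fronts, sort), peel_fronts(kk, nn))
    expect_setequal(unlist(fronts), seq_len(m))  # exactly one level each
  }
})

test_that("crowding_distance: boundaries, interior value, degeneracy", {
  expect_equal(crowding_distance(0.5, 5), Inf)
  expect_equal(crowding_distance(c(0.4, 0.6), c(8, 2)), c(Inf, Inf))
  # 3 collinear equally spaced points: middle = 1.0 per objective
  d <- crowding_distance(c(0.2, 0.4, 0.6), c(30, 20, 10))
  expect_equal(d, c(Inf, 2, Inf))
  # duplicated objective pairs: finite, non-negative, no division error
  d2 <- crowding_distance(c(0.5, 0.5, 0.5, 0.5), c(3, 3, 3, 3))
  expect_false(any(is.nan(d2)))
  expect_true(all(d2 >= 0))
})

test_that("dominance_ratio counts strictly dominated previous solutions", {
  f <- data.frame(kappa = c(0.7, 0.6), n = c(10, 5))
  expect_equal(dominance_ratio(f, f), 0)
  better <- data.frame(kappa = c(0.9), n = c(1))
  expect_equal(dominance_ratio(f, better), 1)
  curr <- data.frame(kappa = c(0.8, 0.6), n = c(10, 5))
  expect_equal(dominance_ratio(f, curr), 0.5)
  expect_error(dominance_ratio(f, f[0, ]), "non-empty")
})

test_that("descriptor_frequency equals mask-matrix column sums", {
  set.seed(17)
  masks <- replicate(6, runif(9) < 0.4, simplify = FALSE)
  freq <- descriptor_frequency(masks, names = paste0("m", 1:9))
  mat <- do.call(rbind, lapply(masks, as.integer))
  expect_equal(freq$count[match(paste0("m", 1:9), freq$descriptor)],
               unname(colSums(mat)))
  all_on <- descriptor_frequency(list(rep(TRUE, 4), rep(TRUE, 4)))
  expect_true(all(all_on$count == 2))
  expect_true(0 %in% descriptor_frequency(list(c(TRUE, FALSE)))$count)
})

test_that("evolve: determinism, caching, constant population, repair", {
  calls <- new.env(); calls$n <- 0L; calls$keys <- character(0)
  ev <- function(mask) {
    stopifnot(any(mask))               # empty masks must never arrive
    calls$n <- calls$n + 1L
    calls$keys <- c(calls$keys, paste(which(mask), collapse = ","))
    0.5 + 0.4 * mean(mask[1:3])        # bits 1-3 informative
  }
  cfg <- ga_config(population_size = 10, generations = 8, seed = 5,
                   p_mut_off = 0.4)    # aggressive off-mutation
  res <- evolve(ev, 12, cfg)

  # identical masks never re-trigger the evaluator
  expect_equal(calls$n, res$cache_stats$evaluations)
  expect_equal(anyDuplicated(calls$keys), 0L)

  expect_length(res$final_population$masks, 10)        # constant size
  expect_length(res$dominance_ratios, 7)               # generations - 1
  expect_length(res$archive, 8)
  expect_equal(vapply(res$log, `[[`, 0L, "generation"), 1:8)

  res2 <- evolve(ev, 12, cfg)
  expect_equal(res2$archive, res$archive)              # same seed, same run
  expect_equal(res2$dominance_ratios, res$dominance_ratios)
})

test_that("evolve with a constant evaluator collapses to minimal masks", {
  ev <- function(mask) 0.7
  res <- evolve(ev, 15, ga_config(10, 12, seed = 2))
  expect_equal(min(res$final_front$n), 1)
  # with kappa flat, only size varies: the deduplicated front is minimal
  expect_true(all(res$final_front$n == 1))
})

test_that("elitism: best kappa at or below any size never degrades", {
  runs <- acceptance_ga_runs()
  arch <- runs[[1]]$result$archive
  for (s in c(2, 5, 10, 20)) {
    best <- vapply(arch, function(fr) {
      v <- fr$kappa[fr$n <= s]
      if (length(v)) max(v) else -Inf
    }, 0)
    expect_true(all(diff(best) >= -1e-12))
  }
})

test_that("GA recovers planted descriptors on easy synthetic data", {
  # small, quick sanity run distinct from the acceptance preset
  spec <- synth_preset("ga", n_pos = 80, n_neg = 80, d_noise = 15,
                       seed = 31)
  tab <- gen_tabular(spec)
  X <- tab$features$values; y <- tab$labels
  folds <- make_folds(y, 5, seed = 31)
  ev <- function(mask) as.numeric(kappa_cv(X, y, mask, folds = folds))
  res <- evolve(ev, ncol(X), ga_config(12, 10, seed = 31))
  best_i <- which.max(res$final_front$kappa)
  picked <- colnames(X)[res$final_front$masks[[best_i]]]
  expect_gte(sum(picked %in% tab$manifest$informative), 2)
})
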