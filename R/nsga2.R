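#' NSGA-II descriptor-subset selection
#'
#' Multi-objective search over binary descriptor masks with two
#' objectives: maximize the 5-fold cross-validated Cohen's kappa of an
#' RBF-SVM trained on the selected descriptors, and minimize the number
#' of selected descriptors.  Internally both objectives are minimized as
#' `(-kappa, n_selected)`.
#'
#' Individuals are fixed-length bit vectors.  Population bookkeeping uses
#' a plain data.frame of objectives plus a list of masks.
#'
#' @name nsga2
NULL

#' Pareto dominance on (kappa, subset size)
#'
#' `a` dominates `b` when `a` is at least as good on both objectives
#' (kappa higher-or-equal, size lower-or-equal) and strictly better on at
#' least one.  Equal points do not dominate each other.
#'
#' @param kappa_a,n_a Objectives of `a`.
#' @param kappa_b,n_b Objectives of `b`.
#' @return Logical.
#' @export
dominates <- function(kappa_a, n_a, kappa_b, n_b) {
  if (anyNA(c(kappa_a, n_a, kappa_b, n_b)))
    stop_data("dominance needs evaluated individuals")
  (kappa_a >= kappa_b && n_a <= n_b) &&
    (kappa_a > kappa_b || n_a < n_b)
}

#' Fast non-dominated sorting
#'
#' Assigns every individual a dominance level: level 1 is the Pareto
#' front; level 2 the front once level 1 is removed; and so on (the
#' standard NSGA-II fast non-dominated sort).
#'
#' @param kappa,n Equal-length objective vectors (kappa maximized, n
#'   minimized).
#' @return List of integer index vectors, one per front, in level order.
#' @export
non_dominated_sort <- function(kappa, n) {
  np <- length(kappa)
  if (np == 0) return(list())
  if (anyNA(kappa) || anyNA(n))
    stop_data("all individuals must be evaluated before sorting")
  dominated_by <- vector("list", np)   # S_p: who p dominates
  n_dom <- integer(np)                 # how many dominate p
  for (p in seq_len(np)) {
    for (q in seq_len(np)) {
      if (p == q) next
      if (dominates(kappa[p], n[p], kappa[q], n[q]))
        dominated_by[[p]] <- c(dominated_by[[p]], q)
      else if (dominates(kappa[q], n[q], kappa[p], n[p]))
        n_dom[p] <- n_dom[p] + 1L
    }
  }
  fronts <- list()
  current <- which(n_dom == 0L)
  while (length(current)) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer(0)
    for (p in current) for (q in dominated_by[[p]]) {
      n_dom[q] <- n_dom[q] - 1L
      if (n_dom[q] == 0L) nxt <- c(nxt, q)
    }
    current <- sort(unique(nxt))
  }
  fronts
}

#' Crowding distance within one front
#'
#' For each objective the front is sorted; the two boundary individuals
#' receive infinite distance and interior ones the sum over objectives of
#' the normalized gap between their neighbors.  An objective with zero
#' range contributes 0 (no division error).
#'
#' @param kappa,n Objective vectors of the front members.
#' @return Numeric distances (may be `Inf`).
#' @export
crowding_distance <- function(kappa, n) {
  m <- length(kappa)
  if (m == 0) stop_data("empty front")
  if (m <= 2) return(rep(Inf, m))
  d <- numeric(m)
  for (obj in list(kappa, n)) {
    o <- order(obj)
    rng <- obj[o[m]] - obj[o[1]]
    d[o[1]] <- Inf
    d[o[m]] <- Inf
    if (rng > 0)
      for (i in 2:(m - 1))
        d[o[i]] <- d[o[i]] + (obj[o[i + 1]] - obj[o[i - 1]]) / rng
  }
  d
}

#' Fraction of a previous front dominated by a current front
#'
#' Convergence diagnostic: the fraction of generation `i-1`'s Pareto
#' solutions dominated by at least one Pareto solution of generation `i`.
#' Identical fronts give 0 (domination is strict).
#'
#' @param prev,curr data.frames with columns `kappa` and `n`.
#' @return Ratio in `[0, 1]`.
#' @export
dominance_ratio <- function(prev, curr) {
  if (nrow(prev) == 0 || nrow(curr) == 0)
    stop_data("fronts must be non-empty")
  dominated <- vapply(seq_len(nrow(prev)), function(i)
    any(vapply(seq_len(nrow(curr)), function(j)
      dominates(curr$kappa[j], curr$n[j], prev$kappa[i], prev$n[i]),
      TRUE)), TRUE)
  mean(dominated)
}

#' Descriptor occurrence counts over a Pareto front
#'
#' Importance measure: how many front members' masks include each
#' descriptor.
#'
#' @param front A front as stored in a [evolve()] archive: list with
#'   `masks` (list of logical vectors) or a plain list of logical masks.
#' @param names Optional descriptor names.
#' @return data.frame `descriptor`, `count`, sorted by decreasing count.
#' @export
descriptor_frequency <- function(front, names = NULL) {
  masks <- if (is.list(front) && !is.null(front$masks)) front$masks
           else front
  if (!length(masks)) stop_data("empty front")
  counts <- Reduce(`+`, lapply(masks, as.integer))
  nm <- names %||% sprintf("d%03d", seq_along(counts))
  out <- data.frame(descriptor = nm, count = counts,
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$descriptor), , drop = FALSE]
}

#' NSGA-II configuration
#'
#' Defaults are the published operator settings: 100 generations,
#' population 50, asymmetric per-bit mutation 0.02 (off-to-on) and 0.2
#' (on-to-off), crossover rate 0.6.  The initial population switches each
#' bit on with probability `p_init_on` (sparse start, matching the
#' small-subset objective).
#'
#' @param population_size Even count, default 50.
#' @param generations Default 100.
#' @param p_mut_on Per-bit 0->1 mutation probability, default 0.02.
#' @param p_mut_off Per-bit 1->0 mutation probability, default 0.2.
#' @param p_crossover Probability a parent pair is recombined, default 0.6.
#' @param p_init_on Initial per-bit on probability, default 0.1.
#' @param seed Integer seed.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 50, generations = 100,
                      p_mut_on = 0.02, p_mut_off = 0.2,
                      p_crossover = 0.6, p_init_on = 0.1, seed = 1) {
  p <- c(p_mut_on, p_mut_off, p_crossover, p_init_on)
  if (any(p < 0 | p > 1)) stop_data("probabilities must be in [0, 1]")
  if (population_size < 2 || population_size %% 2 != 0)
    stop_data("population_size must be even and >= 2")
  if (generations < 1) stop_data("generations must be >= 1")
  structure(list(population_size = population_size,
                 generations = generations, p_mut_on = p_mut_on,
                 p_mut_off = p_mut_off, p_crossover = p_crossover,
                 p_init_on = p_init_on, seed = seed),
            class = "ga_config")
}

mask_key <- function(mask) paste(which(mask), collapse = ",")

# binary tournament on (rank asc, crowding desc); i, j are indices
tournament_pick <- function(rank, crowd, i, j) {
  if (rank[i] < rank[j]) return(i)
  if (rank[j] < rank[i]) return(j)
  if (crowd[i] > crowd[j]) return(i)
  if (crowd[j] > crowd[i]) return(j)
  if (runif(1) < 0.5) i else j
}

#' Run NSGA-II over descriptor masks
#'
#' Standard generational loop: evaluate offspring; merge parents and
#' offspring; fast non-dominated sort; fill the next parent population
#' front by front, the last partially fitting front by descending
#' crowding distance; binary tournament selection on (rank, crowding);
#' uniform crossover with probability `p_crossover` (otherwise parents
#' copied); independent per-bit asymmetric mutation.  Masks that come out
#' empty are repaired by switching one uniformly chosen bit on.  Each
#' mask is evaluated at most once (cache); evaluator failures assign the
#' worst objectives (`kappa = -Inf`) and are logged.
#'
#' @param evaluator Function `mask (logical) -> kappa` (deterministic).
#' @param n_descriptors Mask length.
#' @param config A [ga_config()].
#' @param verbose Print per-generation progress.
#' @return Object of class `nsga2_result`: `archive` (per-generation
#'   level-1 fronts: `masks`, `kappa`, `n`), `dominance_ratios` (length
#'   `generations - 1`), `final_population`, `final_front`,
#'   `cache_stats`, `log`, and the `config`.
#' @export
evolve <- function(evaluator, n_descriptors, config = ga_config(),
                   verbose = FALSE) {
  stopifnot(is.function(evaluator), n_descriptors >= 1)
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L; n_hit <- 0L; failures <- character(0)
  eval_mask <- function(mask) {
    key <- mask_key(mask)
    if (!is.null(cache[[key]])) {
      n_hit <<- n_hit + 1L
      return(cache[[key]])
    }
    n_eval <<- n_eval + 1L
    val <- tryCatch(evaluator(mask), error = function(e) {
      failures <<- c(failures, conditionMessage(e))
      -Inf
    })
    cache[[key]] <- val
    val
  }
  repair <- function(mask) {
    if (!any(mask)) mask[sample.int(length(mask), 1)] <- TRUE
    mask
  }
  mutate <- function(mask) {
    u <- runif(length(mask))
    flip_on <- !mask & u < config$p_mut_on
    flip_off <- mask & u < config$p_mut_off
    mask[flip_on] <- TRUE
    mask[flip_off] <- FALSE
    repair(mask)
  }
  uniform_cx <- function(a, b) {
    take <- runif(length(a)) < 0.5
    c1 <- a; c1[take] <- b[take]
    c2 <- b; c2[take] <- a[take]
    list(repair(c1), repair(c2))
  }

  pop_n <- config$population_size
  with_seed(derive_seed(config$seed, "ga"), {
    # sparse random initial population
    masks <- replicate(pop_n, repair(runif(n_descriptors) <
                                       config$p_init_on),
                       simplify = FALSE)
    kappa <- vapply(masks, eval_mask, 0)
    nsel <- vapply(masks, sum, 0L)

    archive <- vector("list", config$generations)
    log <- vector("list", config$generations)
    dom_ratio <- numeric(0)

    rank <- integer(pop_n); crowd <- numeric(pop_n)
    assign_rank_crowd <- function(kv, nv) {
      fronts <- non_dominated_sort(kv, nv)
      r <- integer(length(kv)); cd <- numeric(length(kv))
      for (lv in seq_along(fronts)) {
        idx <- fronts[[lv]]
        r[idx] <- lv
        cd[idx] <- crowding_distance(kv[idx], nv[idx])
      }
      list(rank = r, crowd = cd, fronts = fronts)
    }

    rc <- assign_rank_crowd(kappa, nsel)
    rank <- rc$rank; crowd <- rc$crowd

    snapshot_front <- function(kv, nv, mk, fronts) {
      idx <- fronts[[1]]
      list(masks = mk[idx], kappa = kv[idx], n = nv[idx])
    }

    for (gen in seq_len(config$generations)) {
      # ---- variation: tournament -> crossover -> mutation ----
      offspring <- vector("list", pop_n)
      oi <- 1L
      while (oi <= pop_n) {
        p1 <- tournament_pick(rank, crowd, sample.int(pop_n, 1),
                              sample.int(pop_n, 1))
        p2 <- tournament_pick(rank, crowd, sample.int(pop_n, 1),
                              sample.int(pop_n, 1))
        if (runif(1) < config$p_crossover) {
          kids <- uniform_cx(masks[[p1]], masks[[p2]])
        } else {
          kids <- list(masks[[p1]], masks[[p2]])
        }
        offspring[[oi]] <- mutate(kids[[1]])
        if (oi + 1L <= pop_n) offspring[[oi + 1L]] <- mutate(kids[[2]])
        oi <- oi + 2L
      }
      off_kappa <- vapply(offspring, eval_mask, 0)
      off_n <- vapply(offspring, sum, 0L)

      # ---- environmental selection on merged population ----
      all_masks <- c(masks, offspring)
      all_kappa <- c(kappa, off_kappa)
      all_n <- c(nsel, off_n)
      fronts <- non_dominated_sort(all_kappa, all_n)
      keep <- integer(0)
      for (f in fronts) {
        if (length(keep) + length(f) <= pop_n) {
          keep <- c(keep, f)
        } else {
          cd <- crowding_distance(all_kappa[f], all_n[f])
          f <- f[order(-cd)]
          keep <- c(keep, f[seq_len(pop_n - length(keep))])
          break
        }
      }
      masks <- all_masks[keep]
      kappa <- all_kappa[keep]
      nsel <- all_n[keep]
      rc <- assign_rank_crowd(kappa, nsel)
      rank <- rc$rank; crowd <- rc$crowd
      archive[[gen]] <- snapshot_front(kappa, nsel, masks, rc$fronts)
      if (gen > 1) {
        prev <- archive[[gen - 1]]
        cur <- archive[[gen]]
        dom_ratio <- c(dom_ratio, dominance_ratio(
          data.frame(kappa = prev$kappa, n = prev$n),
          data.frame(kappa = cur$kappa, n = cur$n)))
      }
      log[[gen]] <- list(generation = gen,
                         front_size = length(archive[[gen]]$kappa),
                         best_kappa = max(archive[[gen]]$kappa),
                         min_size = min(archive[[gen]]$n),
                         dominance_ratio = if (gen > 1)
                           dom_ratio[gen - 1] else NA_real_,
                         evaluations = n_eval, cache_hits = n_hit)
      if (verbose)
        message(sprintf(
          "gen %3d: front %2d, best kappa %.3f, min size %d, dr %s",
          gen, length(archive[[gen]]$kappa), max(archive[[gen]]$kappa),
          min(archive[[gen]]$n),
          if (gen > 1) sprintf("%.3f", dom_ratio[gen - 1]) else "-"))
    }

    # deduplicate the final front by mask
    ff <- archive[[config$generations]]
    dup <- duplicated(vapply(ff$masks, mask_key, ""))
    final_front <- list(masks = ff$masks[!dup], kappa = ff$kappa[!dup],
                        n = ff$n[!dup])

    structure(list(
      archive = archive,
      dominance_ratios = dom_ratio,
      final_population = list(masks = masks, kappa = kappa, n = nsel),
      final_front = final_front,
      cache_stats = list(evaluations = n_eval, cache_hits = n_hit,
                         failures = failures),
      log = log,
      config = config
    ), class = "nsga2_result")
  })
}

#' @export
print.nsga2_result <- function(x, ...) {
  ff <- x$final_front
  cat(sprintf(
    "NSGA-II: %d generations, final front %d solutions (kappa %.3f..%.3f, size %d..%d)\n",
    x$config$generations, length(ff$kappa), min(ff$kappa), max(ff$kappa),
    min(ff$n), max(ff$n)))
  cat(sprintf("  %d evaluations, %d cache hits\n",
              x$cache_stats$evaluations, x$cache_stats$cache_hits))
  invisible(x)
}
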