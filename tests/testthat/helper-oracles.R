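# Independent oracles used across test files.  These deliberately use the
# slowest, most literal formulation so they stay independent of the
# implementation they check.

# Non-dominated sorting by repeated peeling: a point is on the current
# front iff no remaining point dominates it (kappa max, n min).
peel_fronts <- function(kappa, n) {
  remaining <- seq_along(kappa)
  fronts <- list()
  while (length(remaining)) {
    nd <- remaining[vapply(remaining, function(p) {
      !any(vapply(remaining, function(q) {
        q != p &&
          (kappa[q] >= kappa[p] && n[q] <= n[p]) &&
          (kappa[q] > kappa[p] || n[q] < n[p])
      }, TRUE))
    }, TRUE)]
    fronts[[length(fronts) + 1L]] <- sort(nd)
    remaining <- setdiff(remaining, nd)
  }
  fronts
}

# O(n^2) pairwise ROC AUC
auc_pairs <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# element-wise confusion tally
tally_confusion <- function(truth, pred) {
  tp <- fn <- fp <- tn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1L
    else if (truth[i] == 1) fn <- fn + 1L
    else if (pred[i] == 1) fp <- fp + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

# small two-feature blob dataset, linearly separable when sep is large
make_blobs <- function(n_per_class = 30, sep = 4, seed = 1) {
  set.seed(seed)
  X <- cbind(f1 = c(rnorm(n_per_class, -sep / 2),
                    rnorm(n_per_class, sep / 2)),
             f2 = rnorm(2 * n_per_class))
  list(X = X, y = rep(c(0, 1), each = n_per_class))
}
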