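test_that("SMO solution matches an independent quadprog dual solve", {
  skip_if_not_installed("quadprog")
  set.seed(42)
  n <- 40
  X <- cbind(x1 = rnorm(n) + rep(c(-1.2, 1.2), each = n / 2),
             x2 = rnorm(n))
  ys <- rep(c(-1, 1), each = n / 2)
  gamma <- 0.5; Cp <- 2; Cn <- 1
  K <- exp(-gamma * as.matrix(dist(X))^2)
  D <- (ys %o% ys) * K + diag(1e-8, n)
  Amat <- cbind(ys, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), -ifelse(ys > 0, Cp, Cn))
  qp <- quadprog::solve.QP(D, rep(1, n), Amat, bvec, meq = 1)
  a_qp <- pmax(qp$solution, 0)

  fit <- hergsel:::.smo_train(X, ys, Cp, Cn, gamma, 1e-6)
  expect_lt(max(abs(a_qp - fit$alpha)), 1e-3)

  free <- which(a_qp > 1e-6 & a_qp < ifelse(ys > 0, Cp, Cn) - 1e-6)
  b_qp <- mean(ys[free] - (K %*% (a_qp * ys))[free])
  f_qp <- as.numeric(K %*% (a_qp * ys) + b_qp)
  sv <- fit$alpha > 1e-8
  f_smo <- hergsel:::.rbf_decision(X[sv, , drop = FALSE],
                                   (fit$alpha * ys)[sv], fit$b, gamma, X)
  expect_lt(max(abs(f_qp - f_smo)), 1e-4)
})

test_that("train_svm separates separable blobs and guards its inputs", {
  d <- make_blobs(30, sep = 4, seed = 1)
  m <- train_svm(d$X, d$y)
  p <- predict(m, d$X)
  expect_equal(classification_metrics(confusion_counts(d$y, p))$kappa, 1)
  expect_equal(predict(m, d$X, type = "decision") >= 0, p == 1)

  # feature-manifest guard
  Xbad <- d$X; colnames(Xbad) <- c("f2", "f1")
  expect_error(predict(m, Xbad), "manifest")
  expect_error(train_svm(d$X, rep(1, nrow(d$X))), "both classes")
  expect_error(train_svm(d$X, d$y[-1]), "differ")
})

test_that("permutation null: CV kappa of shuffled labels stays near 0", {
  d <- make_blobs(50, sep = 3, seed = 2)
  kappas <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    y_perm <- sample(d$y)
    as.numeric(kappa_cv(d$X, y_perm, k = 5, seed = s))
  }, 0)
  expect_lt(abs(mean(kappas)), 0.15)
})

test_that("class weighting raises sensitivity on imbalanced data", {
  set.seed(8)
  n_pos <- 12; n_neg <- 120
  X <- cbind(f1 = c(rnorm(n_pos, 1.2), rnorm(n_neg, -1.2)),
             f2 = rnorm(n_pos + n_neg))
  y <- c(rep(1, n_pos), rep(0, n_neg))
  folds <- make_folds(y, 4, seed = 3)
  sens_of <- function(cfg) {
    pred <- integer(length(y))
    for (j in 1:4) {
      tr <- folds != j
      m <- train_svm(X[tr, , drop = FALSE], y[tr], cfg)
      pred[!tr] <- predict(m, X[!tr, , drop = FALSE])
    }
    classification_metrics(confusion_counts(y, pred))$sensitivity
  }
  s_weighted <- sens_of(svm_config())                        # ratio = 10
  s_flat <- sens_of(svm_config(class_weight_ratio = 1))
  expect_gt(s_weighted, s_flat)
})

test_that("kappa_cv: LOO matches a brute-force per-sample loop", {
  set.seed(9)
  X <- cbind(a = c(rnorm(6, -1.5), rnorm(6, 1.5)), b = rnorm(12))
  y <- rep(c(0, 1), each = 6)
  folds <- make_folds(y, 6, seed = 2)  # 2 samples per fold, stratified
  got <- kappa_cv(X, y, k = 6, folds = folds)
  manual <- vapply(1:6, function(j) {
    tr <- folds != j
    cfg <- svm_config(gamma = 1 / ncol(X))
    m <- train_svm(X[tr, , drop = FALSE], y[tr], cfg)
    p <- predict(m, X[!tr, , drop = FALSE])
    k <- classification_metrics(confusion_counts(y[!tr], p))$kappa
    if (is.na(k)) 0 else k
  }, 0)
  expect_equal(as.numeric(got), mean(manual))
  expect_equal(attr(got, "per_fold"), manual)
  # determinism and row-permutation invariance with explicit folds
  expect_equal(kappa_cv(X, y, k = 6, seed = 5), kappa_cv(X, y, k = 6, seed = 5))
  perm <- sample(12)
  expect_equal(as.numeric(kappa_cv(X[perm, ], y[perm], folds = folds[perm])),
               as.numeric(got))
})

test_that("informative masks beat size-matched noise masks (paired)", {
  diffs <- vapply(1:5, function(s) {
    spec <- synth_preset("ga", n_pos = 60, n_neg = 60, seed = 100 + s)
    tab <- gen_tabular(spec)
    X <- tab$features$values; y <- tab$labels
    folds <- make_folds(y, 5, seed = s)
    info <- colnames(X) %in% tab$manifest$informative
    noise_mask <- seq_len(ncol(X)) %in% which(!info)[seq_len(sum(info))]
    as.numeric(kappa_cv(X, y, info, folds = folds)) -
      as.numeric(kappa_cv(X, y, noise_mask, folds = folds))
  }, 0)
  expect_true(all(diffs > 0))
})

test_that("make_folds stratifies, is deterministic, and covers classes", {
  y <- c(rep(1, 15), rep(0, 85))
  f <- make_folds(y, 5, seed = 4)
  expect_identical(f, make_folds(y, 5, seed = 4))
  expect_equal(sort(unique(f)), 1:5)
  per_fold_pos <- vapply(1:5, function(j) sum(y[f == j] == 1), 0L)
  expect_true(all(per_fold_pos == 3))
  expect_error(make_folds(y, 1), "k must be")
})

test_that("grid_search ties and winner reproduce an exhaustive re-run", {
  # two tight, far-apart clusters: every grid cell separates perfectly
  set.seed(3)
  d <- list(X = cbind(f1 = c(rnorm(24, -5, 0.1), rnorm(24, 5, 0.1)),
                      f2 = rnorm(48, 0, 0.1)),
            y = rep(c(0, 1), each = 24))
  gs <- grid_search(d$X, d$y, k = 4, seed = 6)
  expect_equal(nrow(gs$table), 9)
  # all cells perfect -> tie broken to smallest C then gamma
  expect_true(all(gs$table$kappa_cv == 1))
  expect_equal(gs$best$C, 0.5)
  expect_equal(gs$best$gamma, 0.5 / ncol(d$X))

  # single-point grid returns it
  g1 <- grid_search(d$X, d$y, C_grid = 2, gamma_scale_grid = 1, k = 4,
                    seed = 6)
  expect_equal(g1$best$C, 2)

  # winner equals an independent exhaustive re-evaluation on the same folds
  d2 <- make_blobs(40, sep = 1.2, seed = 4)
  gs2 <- grid_search(d2$X, d2$y, k = 5, seed = 7)
  redo <- vapply(seq_len(nrow(gs2$table)), function(i)
    as.numeric(kappa_cv(d2$X, d2$y, k = 5,
                        config = svm_config(gs2$table$C[i],
                                            gs2$table$gamma[i]),
                        folds = gs2$folds)), 0)
  expect_equal(gs2$table$kappa_cv, redo)
  expect_equal(gs2$best_kappa, max(redo))
  expect_error(grid_search(d2$X, d2$y, C_grid = numeric(0)), "empty")
})
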