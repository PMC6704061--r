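#' SVM configuration
#'
#' Holds the RBF-SVM hyperparameters.  During genetic-algorithm descriptor
#' selection the solver defaults are used: `C = 1` and `gamma = 1/nx`
#' where `nx` is the number of input features (descriptors plus
#' fingerprint bits when combined); after selection both are tuned by
#' [grid_search()].  `class_weight_ratio` multiplies the penalty `C` for
#' minority-class samples; `NULL` means "derive from the training labels"
#' (majority count / minority count).
#'
#' @param C Slack penalty, positive; default 1.
#' @param gamma RBF width, positive, or `NULL` for the `1/nx` rule.
#' @param class_weight_ratio Positive multiplier on the minority-class
#'   penalty, or `NULL` to derive it from the data, or `1` to disable
#'   weighting.
#' @return Object of class `svm_config`.
#' @export
svm_config <- function(C = 1, gamma = NULL, class_weight_ratio = NULL) {
  if (C <= 0) stop_data("C must be positive")
  if (!is.null(gamma) && gamma <= 0) stop_data("gamma must be positive")
  if (!is.null(class_weight_ratio) && class_weight_ratio <= 0)
    stop_data("class_weight_ratio must be positive")
  structure(list(C = C, gamma = gamma,
                 class_weight_ratio = class_weight_ratio),
            class = "svm_config")
}

#' Train a class-weighted RBF-kernel SVM
#'
#' Fits the soft-margin dual by SMO.  Labels are 0/1 with 1 the positive
#' (inhibitor) class; internally mapped to -1/+1.  The minority class gets
#' penalty `C * class_weight_ratio` (default ratio: majority/minority
#' count in `y`), imposing a heavier cost on minority-class errors.
#'
#' @param X Numeric matrix with named columns (or `feature_table`).
#' @param y Binary 0/1 labels, one per row of `X`.
#' @param config An [svm_config()].
#' @return Object of class `herg_svm` with the support vectors, dual
#'   coefficients, bias, resolved hyperparameters and the feature-name
#'   manifest the model was trained on.
#' @export
train_svm <- function(X, y, config = svm_config()) {
  if (inherits(X, "feature_table")) X <- X$values
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop_data("X rows and y length differ")
  if (!all(y %in% c(0, 1))) stop_data("y must be binary 0/1")
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0)
    stop_data("both classes must be present to train")
  gamma <- config$gamma %||% (1 / ncol(X))
  ratio <- config$class_weight_ratio %||%
    (max(npos, nneg) / min(npos, nneg))
  C_pos <- config$C; C_neg <- config$C
  if (npos <= nneg) C_pos <- C_pos * ratio else C_neg <- C_neg * ratio

  ys <- ifelse(y == 1, 1, -1)
  fit <- .smo_train(X, ys, C_pos, C_neg, gamma)
  sv <- which(fit$alpha > 1e-8)
  structure(list(
    sv = X[sv, , drop = FALSE],
    coef = fit$alpha[sv] * ys[sv],
    b = fit$b,
    gamma = gamma, C = config$C, class_weight_ratio = ratio,
    features = colnames(X),
    n_train = nrow(X), iterations = fit$iterations,
    converged = fit$converged
  ), class = "herg_svm")
}

#' @export
print.herg_svm <- function(x, ...) {
  cat(sprintf(
    "RBF-SVM: %d SVs / %d samples, %d features, C=%g gamma=%g weight=%g\n",
    nrow(x$sv), x$n_train, length(x$features), x$C, x$gamma,
    x$class_weight_ratio))
  invisible(x)
}

#' Predict with a trained SVM
#'
#' Refuses inputs whose feature names or order differ from training.
#'
#' @param object A `herg_svm`.
#' @param newdata Matrix/`feature_table` with the training columns.
#' @param type `"class"` (0/1 at `threshold`) or `"decision"` (raw margin).
#' @param threshold Decision-value cutoff for class predictions; default 0
#'   (the model's native boundary).
#' @param ... Unused.
#' @export
predict.herg_svm <- function(object, newdata, type = c("class", "decision"),
                             threshold = 0, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_table")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) ||
      !identical(colnames(newdata), object$features))
    stop_data("feature names/order differ from the training manifest")
  f <- .rbf_decision(object$sv, object$coef, object$b, object$gamma,
                     newdata)
  if (type == "decision") f else as.integer(f >= threshold)
}

#' Stratified k-fold assignment
#'
#' Assigns each sample to one of `k` folds, stratified by class so every
#' fold carries (near-)proportional class counts.  If a class has fewer
#' members than folds the assignment is re-drawn with an incremented seed
#' until every fold contains both classes (logged via warning), erroring
#' after 25 attempts.
#'
#' @param y Binary 0/1 labels.
#' @param k Number of folds (`>= 2`).
#' @param seed Integer seed.
#' @return Integer fold id per sample, values in `1..k`.
#' @export
make_folds <- function(y, k = 5, seed = 1) {
  if (k < 2) stop_data("k must be >= 2")
  n <- length(y)
  if (k > n) stop_data("more folds than samples")
  for (attempt in 0:24) {
    folds <- with_seed(derive_seed(seed + attempt, "folds"), {
      f <- integer(n)
      for (cl in unique(y)) {
        i <- which(y == cl)
        f[i] <- sample(rep_len(seq_len(k), length(i)))
      }
      f
    })
    ok <- all(vapply(seq_len(k), function(j)
      length(unique(y[folds == j])) == 2, TRUE))
    if (ok) {
      if (attempt > 0)
        warning(sprintf("fold assignment re-drawn %d time(s): %s",
                        attempt, "a fold lacked a class"))
      return(folds)
    }
  }
  stop_data("could not build folds with both classes present")
}

#' Mean Cohen's kappa over stratified k-fold cross-validation
#'
#' The genetic algorithm's performance objective.  Selects the columns of
#' `X` given by `mask`, builds a stratified `k`-fold partition (or uses an
#' explicit `folds` assignment), trains a class-weighted RBF-SVM on each
#' training part with `gamma = 1/nx` (`nx` = number of selected columns)
#' unless a fixed gamma is supplied, and returns the arithmetic mean of
#' the per-fold kappa values.  The class-weight ratio is recomputed from
#' each training fold.
#'
#' @param X Feature matrix (descriptors, optionally with fingerprint-bit
#'   columns appended).
#' @param y Binary 0/1 labels.
#' @param mask Logical/0-1 vector over columns of `X`, or `NULL` for all
#'   columns.
#' @param k Folds, default 5.
#' @param config [svm_config()]; its `gamma = NULL` engages the `1/nx`
#'   rule on the masked column count.
#' @param seed Seed for the fold draw (ignored when `folds` given).
#' @param folds Optional explicit fold assignment from [make_folds()].
#' @return Mean kappa, with attributes `per_fold` (numeric k-vector) and
#'   `folds`.
#' @export
kappa_cv <- function(X, y, mask = NULL, k = 5, config = svm_config(),
                     seed = 1, folds = NULL) {
  if (inherits(X, "feature_table")) X <- X$values
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (is.null(mask)) mask <- rep(TRUE, ncol(X))
  mask <- as.logical(mask)
  if (length(mask) != ncol(X)) stop_data("mask length must match columns")
  if (!any(mask)) stop_data("mask selects no columns")
  Xs <- X[, mask, drop = FALSE]
  if (is.null(folds)) folds <- make_folds(y, k, seed)
  k <- max(folds)
  cfg <- config
  if (is.null(cfg$gamma)) cfg$gamma <- 1 / ncol(Xs)
  per_fold <- vapply(seq_len(k), function(j) {
    tr <- folds != j
    m <- train_svm(Xs[tr, , drop = FALSE], y[tr], cfg)
    pred <- predict(m, Xs[!tr, , drop = FALSE])
    km <- classification_metrics(confusion_counts(y[!tr], pred))$kappa
    if (is.na(km)) 0 else km
  }, 0)
  structure(mean(per_fold), per_fold = per_fold, folds = folds)
}

#' Grid search over C and gamma by cross-validated kappa
#'
#' Evaluates every combination of `C_grid` and `gamma_scale_grid / nx`
#' (`nx` = number of columns of `X`) with [kappa_cv()] on one shared fold
#' partition so the comparison is paired.  Ties are broken toward the
#' smaller `C`, then the smaller gamma.
#'
#' @param X Feature matrix; @param y binary labels.
#' @param C_grid Candidate penalties, default `c(0.5, 1, 2)`.
#' @param gamma_scale_grid Candidate gamma numerators, default
#'   `c(0.5, 1, 2)` (each used as `scale / nx`).
#' @param k Folds; @param seed fold seed.
#' @param config Base [svm_config()] supplying the class-weight policy.
#' @return List with `best` (an `svm_config` with resolved gamma),
#'   `best_kappa`, and `table` (data.frame of all grid cells).
#' @export
grid_search <- function(X, y, C_grid = c(0.5, 1, 2),
                        gamma_scale_grid = c(0.5, 1, 2), k = 5, seed = 1,
                        config = svm_config()) {
  if (inherits(X, "feature_table")) X <- X$values
  X <- as.matrix(X)
  if (!length(C_grid) || !length(gamma_scale_grid))
    stop_data("empty hyperparameter grid")
  nx <- ncol(X)
  folds <- make_folds(y, k, seed)
  grid <- expand.grid(C = sort(C_grid),
                      gamma_scale = sort(gamma_scale_grid))
  grid$gamma <- grid$gamma_scale / nx
  grid$kappa_cv <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$C <- grid$C[i]; cfg$gamma <- grid$gamma[i]
    as.numeric(kappa_cv(X, y, NULL, k, cfg, folds = folds))
  }, 0)
  # argmax kappa; exact ties resolved toward smaller C, then smaller gamma
  cand <- which(grid$kappa_cv == max(grid$kappa_cv))
  best_i <- cand[order(grid$C[cand], grid$gamma[cand])][1]
  best <- config
  best$C <- grid$C[best_i]; best$gamma <- grid$gamma[best_i]
  class(best) <- "svm_config"
  list(best = best, best_kappa = grid$kappa_cv[best_i], table = grid,
       folds = folds)
}
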