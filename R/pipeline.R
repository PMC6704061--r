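#' Rescore Pareto descriptor sets combined with fingerprints
#'
#' For each mask in a final Pareto front, builds the feature matrix
#' "selected descriptors + fingerprint bits", recomputes the
#' cross-validated kappa on one shared fold partition (so all candidates
#' are compared on identical folds), and also scores the fingerprint-only
#' baseline (empty descriptor set) as a reference.  The `1/nx` gamma rule
#' counts descriptors plus fingerprint width.
#'
#' @param front Final front from [evolve()] (`masks`, `kappa`, `n`).
#' @param features Descriptor matrix or `feature_table` (selection-set
#'   rows).
#' @param fp Fingerprint-bit 0/1 matrix with the same rows (see
#'   `fp_matrix` via [gen_fingerprints()]/[parse_fingerprints()]).
#' @param labels Binary 0/1 labels.
#' @param k Folds, default 5.
#' @param seed Fold seed (fresh folds, fixed for the whole stage).
#' @param config Base [svm_config()].
#' @return data.frame of class `candidate_set`: one row per unique mask
#'   plus the baseline, columns `n_desc`, `kappa_cv`, `baseline`
#'   (logical), and a `masks` attribute (list of logical vectors).
#' @export
combine_and_rescore <- function(front, features, fp, labels, k = 5,
                                seed = 1, config = svm_config()) {
  if (inherits(features, "feature_table")) features <- features$values
  features <- as.matrix(features)
  fp <- as.matrix(fp)
  if (nrow(features) != nrow(fp) || nrow(fp) != length(labels))
    stop_data("features, fingerprints and labels must align by row")
  if (!length(front$masks)) stop_data("empty Pareto front")
  folds <- make_folds(labels, k, derive_seed(seed, "rescore"))
  masks <- c(list(rep(FALSE, ncol(features))), front$masks)
  key <- vapply(masks, mask_key, "")
  keep <- !duplicated(key)
  masks <- masks[keep]
  rows <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    X <- cbind(features[, m, drop = FALSE], fp)
    kcv <- kappa_cv(X, labels, NULL, k, config, folds = folds)
    data.frame(n_desc = sum(m), kappa_cv = as.numeric(kcv),
               baseline = !any(m))
  })
  out <- do.call(rbind, rows)
  o <- order(out$n_desc, -out$kappa_cv)
  out <- out[o, , drop = FALSE]
  attr(out, "masks") <- masks[o]
  rownames(out) <- NULL
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Pick per-size-bin candidates and enforce the kappa staircase
#'
#' Two rules applied to scored candidates: (1) within each
#' right-closed size bin `(0,10], (10,20], ...` keep the candidate with
#' the highest kappa (ties to the smaller set); (2) scanning by
#' increasing size, eliminate any candidate whose kappa does not strictly
#' exceed that of every retained smaller candidate.  The result is a
#' strict staircase: sizes and kappas both strictly increase.  The
#' fingerprint-only baseline (size 0) is never itself a candidate.
#'
#' @param scored A `candidate_set` from [combine_and_rescore()], or any
#'   data.frame with `n_desc` and `kappa_cv` columns.
#' @param bin_width Size-bin width, default 10.
#' @return Subset of `scored` (same class), the retained candidates in
#'   increasing size order; the `masks` attribute is subset accordingly
#'   when present.
#' @export
pick_candidates <- function(scored, bin_width = 10) {
  if (!nrow(scored)) stop_data("no candidates to pick from")
  masks <- attr(scored, "masks")
  df <- as.data.frame(scored)
  df$.row <- seq_len(nrow(df))
  df <- df[df$n_desc > 0, , drop = FALSE]
  if (!nrow(df)) stop_data("no non-baseline candidates")
  df$bin <- ceiling(df$n_desc / bin_width)   # right-closed bins
  per_bin <- do.call(rbind, lapply(split(df, df$bin), function(g) {
    g[order(-g$kappa_cv, g$n_desc), , drop = FALSE][1, , drop = FALSE]
  }))
  per_bin <- per_bin[order(per_bin$n_desc), , drop = FALSE]
  keep <- logical(nrow(per_bin))
  running_max <- -Inf
  for (i in seq_len(nrow(per_bin))) {
    if (per_bin$kappa_cv[i] > running_max) {
      keep[i] <- TRUE
      running_max <- per_bin$kappa_cv[i]
    }
  }
  sel <- per_bin$.row[keep]
  out <- scored[sel, setdiff(names(scored), c(".row", "bin")),
                drop = FALSE]
  if (!is.null(masks)) attr(out, "masks") <- masks[sel]
  rownames(out) <- NULL
  class(out) <- class(scored)
  out
}

#' Finalize a candidate: grid search, train, cross-validation report
#'
#' Tunes `C` and gamma by [grid_search()] on the full training rows,
#' trains the final class-weighted SVM with the winning configuration,
#' and reports per-fold and pooled cross-validation statistics.
#'
#' @param X Feature matrix for the candidate (descriptors already
#'   combined with fingerprint bits as desired).
#' @param y Binary 0/1 labels.
#' @param seed Fold seed.
#' @param k Folds, default 5.
#' @param config Base [svm_config()].
#' @return List of class `final_model`: `model` (a `herg_svm`), `best`
#'   config, `cv_table` (grid), `per_fold` kappa, `pooled_cm`,
#'   `pooled_metrics` (metrics of the pooled CV confusion counts).
#' @export
finalize <- function(X, y, seed = 1, k = 5, config = svm_config()) {
  X <- as.matrix(X)
  gs <- grid_search(X, y, k = k, seed = derive_seed(seed, "final-grid"),
                    config = config)
  folds <- gs$folds
  # pooled out-of-fold confusion counts under the winning config
  pred <- integer(length(y))
  per_fold <- numeric(max(folds))
  for (j in seq_len(max(folds))) {
    tr <- folds != j
    m <- train_svm(X[tr, , drop = FALSE], y[tr], gs$best)
    pred[!tr] <- predict(m, X[!tr, , drop = FALSE])
    per_fold[j] <- classification_metrics(
      confusion_counts(y[!tr], pred[!tr]))$kappa
  }
  pooled_cm <- confusion_counts(y, pred)
  model <- train_svm(X, y, gs$best)
  structure(list(model = model, best = gs$best, cv_table = gs$table,
                 per_fold = per_fold, pooled_cm = pooled_cm,
                 pooled_metrics = classification_metrics(pooled_cm)),
            class = "final_model")
}

#' @export
print.final_model <- function(x, ...) {
  cat(sprintf("final model: C=%g gamma=%g | CV %s\n", x$best$C,
              x$best$gamma, format(x$pooled_metrics)))
  invisible(x)
}

#' End-to-end model-building pipeline on synthetic data
#'
#' Orchestrates the full recipe on a generated dataset with known ground
#' truth: assay-record curation and labeling, stratified train/test
#' split, majority-class trimming by fingerprint clustering to a
#' class-balanced selection set, descriptor filtering, NSGA-II descriptor
#' selection scored by cross-validated kappa, recombination of the Pareto
#' descriptor sets with fingerprint bits, per-size-bin candidate picking,
#' grid-searched final training on the full (imbalanced) training rows,
#' held-out test evaluation, and an applicability-domain report.
#'
#' @param spec A [synth_spec()]; its `seed` drives every stage.
#' @param ga A [ga_config()] (scale `population_size`/`generations` to
#'   the problem).
#' @param test_fraction Held-out fraction, default 0.3.
#' @param verbose Print stage progress.
#' @return List of class `herg_pipeline`: the per-stage artifacts
#'   (`curation`, `split`, `filtered`, `selection`, `candidates`,
#'   `picked`, `final`, `test_metrics`, `ad`, `manifest`).
#' @export
run_pipeline <- function(spec = synth_preset("imbalanced"),
                         ga = ga_config(population_size = 20,
                                        generations = 20,
                                        seed = spec$seed),
                         test_fraction = 0.3, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  tab <- gen_tabular(spec)
  fps <- gen_fingerprints(spec, tab$labels)
  assays <- gen_assay_records(spec, tab$labels,
                              tab$manifest$compound_keys)
  say("curating %d assay records", nrow(assays$records))
  cur <- integrate_assays(assays$records)
  labeled <- cur$labels[cur$labels$label != "excluded", , drop = FALSE]
  split <- split_train_test(labeled, test_fraction, seed = spec$seed)

  key_idx <- function(keys) match(keys, tab$manifest$compound_keys)
  tr_i <- key_idx(split$train$compound_key)
  te_i <- key_idx(split$test$compound_key)
  y_tr <- as.integer(split$train$label == "inhibitor")
  y_te <- as.integer(split$test$label == "inhibitor")

  say("filtering descriptors")
  ft_tr <- feature_table(tab$features$values[tr_i, , drop = FALSE],
                         split$train$compound_key)
  filtered <- filter_descriptors(ft_tr)

  # class-balanced selection set: trim the majority class by clustering
  min_cl <- if (sum(y_tr == 1) <= sum(y_tr == 0)) 1L else 0L
  minority <- which(y_tr == min_cl)
  majority <- which(y_tr != min_cl)
  fps_tr <- fps[tr_i]
  reps <- trim_majority_by_clustering(fps_tr[majority],
                                      length(minority),
                                      seed = spec$seed)
  sel_rows <- sort(c(minority, majority[reps]))
  X_sel <- filtered$values[sel_rows, , drop = FALSE]
  y_sel <- y_tr[sel_rows]
  say("selection set: %d rows (%d/%d), %d descriptors",
      length(y_sel), sum(y_sel == 1), sum(y_sel == 0), ncol(X_sel))

  folds_sel <- make_folds(y_sel, 5, derive_seed(spec$seed, "ga-folds"))
  evaluator <- function(mask)
    as.numeric(kappa_cv(X_sel, y_sel, mask, folds = folds_sel))
  say("running NSGA-II (%d x %d)", ga$population_size, ga$generations)
  selection <- evolve(evaluator, ncol(X_sel), ga, verbose = verbose)

  say("recombining Pareto sets with fingerprints")
  fpm_tr <- fp_matrix(fps_tr, fps$width)
  candidates <- combine_and_rescore(selection$final_front,
                                    filtered$values, fpm_tr, y_tr,
                                    seed = spec$seed)
  picked <- pick_candidates(candidates)
  best <- nrow(picked)  # largest retained = highest kappa by staircase
  best_mask <- attr(picked, "masks")[[best]]
  say("finalizing candidate with %d descriptors", sum(best_mask))
  X_final <- cbind(filtered$values[, best_mask, drop = FALSE], fpm_tr)
  final <- finalize(X_final, y_tr, seed = spec$seed)

  fpm_te <- fp_matrix(fps[te_i], fps$width)
  X_te <- cbind(tab$features$values[te_i, filtered$descriptors,
                                    drop = FALSE][, best_mask,
                                                  drop = FALSE],
                fpm_te)
  colnames(X_te) <- colnames(X_final)
  pred_te <- predict(final$model, X_te)
  test_metrics <- classification_metrics(confusion_counts(y_te, pred_te))
  sims <- max_similarities(fps[te_i], fps_tr)
  ad <- ad_report(sims, pred_te, y_te)

  structure(list(curation = cur, split = split, filtered = filtered,
                 selection = selection, candidates = candidates,
                 picked = picked, final = final,
                 best_mask = best_mask,
                 test_metrics = test_metrics, ad = ad,
                 manifest = tab$manifest, spec = spec),
            class = "herg_pipeline")
}

#' @export
print.herg_pipeline <- function(x, ...) {
  cat("hERG model pipeline\n")
  print(x$curation)
  cat(sprintf("  selected %d descriptors; test %s\n", sum(x$best_mask),
              format(x$test_metrics)))
  invisible(x)
}
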