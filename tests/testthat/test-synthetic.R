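test_that("synth_spec validates and generators are pure in (spec, seed)", {
  expect_error(synth_spec(effect_size = 1.5, d_informative = 0),
               "informative")
  expect_error(synth_spec(d_informative = 0, d_correlated_copies = 2,
                          effect_size = 0), "parents")
  expect_error(synth_spec(fp_width = 8, fp_informative_bits = 8),
               "exceed")
  expect_error(synth_spec(fp_on_rate = 1.5), "probabilit")

  spec <- synth_preset("ga", seed = 42)
  t1 <- gen_tabular(spec); t2 <- gen_tabular(spec)
  expect_identical(t1, t2)
  f1 <- gen_fingerprints(spec, t1$labels)
  expect_identical(f1, gen_fingerprints(spec, t1$labels))
  a1 <- gen_assay_records(spec, t1$labels)
  expect_identical(a1, gen_assay_records(spec, t1$labels))
})

test_that("gen_tabular plants the advertised structure", {
  spec <- synth_spec(n_pos = 200, n_neg = 200, d_informative = 5,
                     d_noise = 20, d_correlated_copies = 3,
                     d_zero_variance = 2, effect_size = 1.5, seed = 3)
  tab <- gen_tabular(spec)
  X <- tab$features$values
  expect_equal(dim(X), c(400, 30))
  man <- tab$manifest

  # informative columns separate classes by ~effect_size
  for (nm in man$informative) {
    d <- mean(X[tab$labels == 1, nm]) - mean(X[tab$labels == 0, nm])
    expect_gt(d, 0.9)
  }
  # copies correlate > 0.9 with their parents
  for (nm in man$copies)
    expect_gt(abs(cor(X[, nm], X[, man$copy_parent[[nm]]])), 0.9)
  expect_true(all(apply(X[, man$zero_variance, drop = FALSE], 2, var) == 0))

  # filter_descriptors drops exactly the constants and the copies
  filt <- filter_descriptors(tab$features)
  log <- filt$dropped_log
  expect_setequal(log$column[log$stage == "variance"], man$zero_variance)
  expect_setequal(log$column[log$stage == "correlation"], man$copies)
  expect_equal(ncol(filt$values), 25)
})

test_that("effect_size 0 gives a null dataset", {
  spec <- synth_spec(n_pos = 60, n_neg = 60, d_informative = 0, d_noise = 8,
                     d_correlated_copies = 0, d_zero_variance = 0,
                     effect_size = 0, seed = 5)
  tab <- gen_tabular(spec)
  k <- as.numeric(kappa_cv(tab$features$values, tab$labels, seed = 5))
  expect_lt(abs(k), 0.25)
})

test_that("fingerprints carry class signal iff informative bits exist", {
  spec <- synth_preset("ga", n_pos = 50, n_neg = 50, seed = 6)
  labels <- c(rep(1, 50), rep(0, 50))
  seps <- vapply(1:3, function(s) {
    sp <- synth_preset("ga", n_pos = 50, n_neg = 50, seed = 6 + s)
    fps <- gen_fingerprints(sp, labels)
    S <- hergsel:::tanimoto_cross(fps, fps)
    same <- outer(labels, labels, "==") & upper.tri(S)
    diff <- outer(labels, labels, "!=") & upper.tri(S)
    mean(S[same]) - mean(S[diff])
  }, 0)
  expect_true(all(seps > 0))

  # no informative bits -> held-out AUROC ~ 0.5
  sp0 <- synth_spec(n_pos = 60, n_neg = 60, d_informative = 1,
                    fp_informative_bits = 0, fp_width = 64,
                    fp_on_rate = 0.15, seed = 9)
  fps0 <- gen_fingerprints(sp0, labels <- c(rep(1, 60), rep(0, 60)))
  M <- hergsel:::fp_matrix(fps0, 64)
  tr <- c(1:40, 61:100); te <- setdiff(1:120, tr)
  m <- train_svm(M[tr, ], labels[tr])
  auc <- roc_auc(predict(m, M[te, ], type = "decision"), labels[te])
  expect_lt(abs(auc - 0.5), 0.2)

  # never-empty guarantee even with zero background rate
  spz <- synth_spec(n_pos = 5, n_neg = 5, fp_informative_bits = 0,
                    fp_on_rate = 0, fp_width = 16, seed = 2)
  fz <- gen_fingerprints(spz, rep(c(1, 0), 5))
  expect_true(all(lengths(fz$bits) >= 1))
})

test_that("assay generator ground truth survives curation", {
  labels <- rep(c(1, 0), 60)
  # conflict_rate 0: every label recovered
  sp <- synth_spec(n_pos = 60, n_neg = 60, conflict_rate = 0, seed = 11)
  g <- gen_assay_records(sp, labels)
  cur <- integrate_assays(g$records)
  expect_equal(cur$report$label_counts$excluded, 0L)
  got <- cur$labels$label[match(g$manifest$compound_key,
                                cur$labels$compound_key)]
  expect_equal(as.integer(got == "inhibitor"), labels)

  # IC50 priority: planted IC50-vs-percent disagreements resolve to truth
  expect_gt(sum(g$manifest$ic50_priority_planted), 0)

  # conflict_rate 1: exact 2-of-3 splits, every compound excluded
  sp1 <- synth_spec(n_pos = 20, n_neg = 20, conflict_rate = 1, seed = 12)
  g1 <- gen_assay_records(sp1, rep(c(1, 0), 20))
  cur1 <- integrate_assays(g1$records)
  expect_true(all(cur1$labels$label == "excluded"))

  # planted conflicts are exactly the excluded set at intermediate rates
  sp5 <- synth_spec(n_pos = 40, n_neg = 40, conflict_rate = 0.3, seed = 13)
  g5 <- gen_assay_records(sp5, rep(c(1, 0), 40))
  cur5 <- integrate_assays(g5$records)
  excluded <- cur5$labels$compound_key[cur5$labels$label == "excluded"]
  expect_setequal(excluded,
                  g5$manifest$compound_key[g5$manifest$conflicted])
})
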