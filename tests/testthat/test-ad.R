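rand_fp <- function(width = 64, lambda = 10)
  sort(sample(0:(width - 1), min(width, rpois(1, lambda) + 1)))

test_that("tanimoto: worked values, symmetry, empty convention", {
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto(1:5, 1:5), 1)
  expect_equal(tanimoto(1:3, 7:9), 0)
  expect_equal(tanimoto(integer(0), integer(0)), 0)
  expect_equal(tanimoto(integer(0), integer(0), empty_value = 1), 1)
  expect_equal(tanimoto(integer(0), 1:3), 0)
  set.seed(23)
  for (rep in 1:20) {
    a <- rand_fp(); b <- rand_fp()
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    expect_equal(tanimoto(a, a), 1)
  }
})

test_that("1 - tanimoto obeys the triangle inequality (Jaccard metric)", {
  set.seed(29)
  for (rep in 1:200) {
    a <- rand_fp(); b <- rand_fp(); cc <- rand_fp()
    dab <- 1 - tanimoto(a, b); dbc <- 1 - tanimoto(b, cc)
    dac <- 1 - tanimoto(a, cc)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("max_sim_to_train: exact scan, ties to lowest index", {
  set.seed(31)
  train <- fingerprint_set(replicate(100, rand_fp(), simplify = FALSE),
                           width = 64)
  q <- rand_fp()
  got <- max_sim_to_train(q, train)
  brute <- vapply(train$bits, function(b) tanimoto(q, b), 0)
  expect_equal(got$similarity, max(brute))
  expect_equal(got$index, which.max(brute))  # which.max = lowest argmax

  # query present in training -> 1.0 ; disjoint -> 0.0
  expect_equal(max_sim_to_train(train$bits[[40]], train)$similarity, 1)
  far <- fingerprint_set(list(c(0, 1), c(2, 3)), width = 64)
  expect_equal(max_sim_to_train(c(60, 61), far)$similarity, 0)
  expect_error(max_sim_to_train(q, fingerprint_set(list())), "empty")

  # ties: two identical training fingerprints, argmax is the first
  twin <- fingerprint_set(list(c(5, 6), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(max_sim_to_train(c(1, 2, 3), twin)$index, 2)

  # bulk path agrees with the per-query scan
  queries <- fingerprint_set(replicate(15, rand_fp(), simplify = FALSE),
                             width = 64)
  bulk <- max_similarities(queries, train)
  solo <- vapply(queries$bits, function(b)
    max_sim_to_train(b, train)$similarity, 0)
  expect_equal(bulk, solo)
})

test_that("ad_report bins, partitions, and pools exactly", {
  sims <- c(0.05, 0.15, 0.15, 0.35, 0.55, 0.6, 0.65, 0.85, 0.95, 1.0)
  tru <- c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1)
  prd <- c(0, 1, 1, 0, 0, 1, 0, 1, 1, 1)
  rep_ <- ad_report(sims, prd, tru, threshold = 0.6)

  # bin memberships equal direct interval checks (last bin closed)
  expect_equal(rep_$bins$n,
               vapply(seq_len(10), function(b) {
                 lo <- (b - 1) / 10; hi <- b / 10
                 sum(if (b < 10) sims >= lo & sims < hi
                     else sims >= lo & sims <= hi)
               }, 0L))
  expect_equal(sum(rep_$bins$n), 10)

  # inside = sim >= 0.6 (closed), outside strict
  expect_equal(rep_$inside$n, sum(sims >= 0.6))
  expect_equal(rep_$outside$n, sum(sims < 0.6))

  # pooled inside+outside confusion equals global confusion exactly
  pool <- mapply(function(a, b) a + b,
                 unclass(rep_$inside$cm), unclass(rep_$outside$cm))
  expect_equal(pool, unlist(unclass(rep_$global$cm)))
  # bins pool to global too
  expect_equal(colSums(rep_$bins[, c("tp", "fn", "fp", "tn")]),
               unlist(unclass(rep_$global$cm))[c("tp", "fn", "fp", "tn")])

  # all similarities 1 -> outside empty, inside metrics = global metrics
  allin <- ad_report(rep(1, 10), prd, tru)
  expect_equal(allin$outside$n, 0L)
  expect_equal(allin$inside$metrics, allin$global$metrics)

  # threshold 0 -> everything inside
  zero <- ad_report(sims, prd, tru, threshold = 0)
  expect_equal(zero$inside$n, 10L)
  expect_equal(zero$outside$n, 0L)

  # a bin lacking a class reports NA statistics, not 0
  one_bin <- ad_report(rep(0.25, 4), c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_true(is.na(one_bin$bins$specificity[3]))

  expect_error(ad_report(sims, prd[-1], tru), "equal length")
  expect_error(ad_report(c(sims[-1], 1.2), prd, tru), "0, 1")
})
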