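#' Specification for synthetic benchmark data
#'
#' Describes a synthetic two-class dataset with known ground truth that
#' emulates the structure of a curated hERG assay collection: informative
#' descriptors separating the classes by a location shift, pure-noise
#' descriptors, near-duplicate (highly correlated) descriptor copies,
#' zero-variance descriptors, class-dependent fingerprint bits, and
#' compounds with contradictory assay reports.
#'
#' Two presets are provided. `"imbalanced"` mirrors the curated
#' collection's roughly 1:28 inhibitor:inactive ratio (50 positives, 1400
#' negatives); `"ga"` mirrors the trimmed, class-balanced selection set
#' used during descriptor search (200 + 200, 30 descriptors of which 5
#' informative).
#'
#' @param n_pos,n_neg Class sizes.
#' @param d_informative,d_noise,d_correlated_copies,d_zero_variance
#'   Descriptor counts by role.
#' @param effect_size Standardized mean difference between classes on
#'   informative descriptors (default 1.5).
#' @param fp_width Fingerprint bit-space width.
#' @param fp_informative_bits Number of class-dependent bits.
#' @param fp_on_rate Background per-bit on probability.
#' @param conflict_rate Probability a compound receives contradictory
#'   assay reports.
#' @param seed Integer seed.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(n_pos = 50, n_neg = 1400, d_informative = 5,
                       d_noise = 20, d_correlated_copies = 3,
                       d_zero_variance = 2, effect_size = 1.5,
                       fp_width = 128, fp_informative_bits = 8,
                       fp_on_rate = 0.05, conflict_rate = 0.05,
                       seed = 1) {
  if (any(c(n_pos, n_neg, d_informative, d_noise, d_correlated_copies,
            d_zero_variance, fp_width, fp_informative_bits) < 0))
    stop_data("counts must be non-negative")
  if (any(c(fp_on_rate, conflict_rate) < 0 |
          c(fp_on_rate, conflict_rate) > 1))
    stop_data("rates must be probabilities")
  if (effect_size < 0) stop_data("effect_size must be >= 0")
  if (effect_size > 0 && d_informative < 1)
    stop_data("effect_size > 0 needs at least one informative descriptor")
  if (d_correlated_copies > 0 && d_informative < 1)
    stop_data("correlated copies need informative parents")
  if (fp_width <= fp_informative_bits)
    stop_data("fp_width must exceed fp_informative_bits")
  structure(as.list(environment()), class = "synth_spec")
}

#' @rdname synth_spec
#' @param preset `"imbalanced"` or `"ga"`.
#' @param ... Overrides passed to [synth_spec()].
#' @export
synth_preset <- function(preset = c("imbalanced", "ga"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    imbalanced = list(),
    ga = list(n_pos = 200, n_neg = 200, d_informative = 5, d_noise = 25,
              d_correlated_copies = 0, d_zero_variance = 0))
  do.call(synth_spec, modifyList(base, list(...)))
}

#' Generate a descriptor table with planted structure
#'
#' Informative descriptors are drawn with class means `+/- effect_size/2`
#' and unit spread; noise descriptors are class-independent standard
#' normals; each correlated copy is an informative parent plus small
#' jitter (sd 0.2, giving sample `|r| > 0.9`); zero-variance descriptors
#' are constant.  Column order: informative, noise, copies, constant.
#'
#' @param spec A [synth_spec()].
#' @return List: `features` (a [feature_table()]), `labels` (0/1,
#'   positives first), and `manifest` naming every planted column and
#'   each copy's parent.
#' @export
gen_tabular <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(derive_seed(spec$seed, "tabular"), {
    n <- spec$n_pos + spec$n_neg
    labels <- c(rep(1, spec$n_pos), rep(0, spec$n_neg))
    shift <- ifelse(labels == 1, spec$effect_size / 2,
                    -spec$effect_size / 2)
    cols <- list()
    info_names <- if (spec$d_informative)
      sprintf("inf_%02d", seq_len(spec$d_informative)) else character(0)
    for (nm in info_names) cols[[nm]] <- rnorm(n) + shift
    noise_names <- if (spec$d_noise)
      sprintf("noise_%02d", seq_len(spec$d_noise)) else character(0)
    for (nm in noise_names) cols[[nm]] <- rnorm(n)
    copy_parent <- character(0)
    copy_names <- if (spec$d_correlated_copies)
      sprintf("copy_%02d", seq_len(spec$d_correlated_copies))
      else character(0)
    for (i in seq_along(copy_names)) {
      parent <- info_names[(i - 1L) %% spec$d_informative + 1L]
      copy_parent[copy_names[i]] <- parent
      cols[[copy_names[i]]] <- cols[[parent]] + rnorm(n, sd = 0.2)
    }
    const_names <- if (spec$d_zero_variance)
      sprintf("const_%02d", seq_len(spec$d_zero_variance)) else character(0)
    for (nm in const_names) cols[[nm]] <- rep(1, n)
    m <- do.call(cbind, cols)
    keys <- sprintf("SYN%06d", seq_len(n))
    list(features = feature_table(m, keys), labels = labels,
         manifest = list(informative = info_names, noise = noise_names,
                         copies = copy_names, copy_parent = copy_parent,
                         zero_variance = const_names,
                         compound_keys = keys))
  })
}

#' Generate class-dependent binary fingerprints
#'
#' Background bits switch on with `fp_on_rate`; the first
#' `fp_informative_bits` bit positions are class-dependent (on-rate 0.6
#' for positives, 0.1 for negatives), so within-class Tanimoto similarity
#' exceeds between-class similarity.  A compound whose draw comes out
#' empty gets one deterministic background bit so fingerprints are never
#' empty.
#'
#' @param spec A [synth_spec()].
#' @param labels Binary 0/1 vector, one per compound.
#' @return A [fingerprint_set()] of `length(labels)` fingerprints.
#' @export
gen_fingerprints <- function(spec, labels) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(derive_seed(spec$seed, "fingerprints"), {
    w <- spec$fp_width
    ni <- spec$fp_informative_bits
    bits <- lapply(seq_along(labels), function(i) {
      on_rate_inf <- if (labels[i] == 1) 0.6 else 0.1
      inf_on <- if (ni) which(runif(ni) < on_rate_inf) - 1L else integer(0)
      bg <- ni + which(runif(w - ni) < spec$fp_on_rate) - 1L
      on <- sort(c(inf_on, bg))
      if (!length(on)) on <- ni + (i - 1L) %% (w - ni)
      on
    })
    fingerprint_set(bits, width = w)
  })
}

#' Generate assay records exercising the curation rules
#'
#' Each compound receives 1-4 records split between IC50 (uM) and percent
#' inhibition at 10 uM, sampled on the correct side of the activity
#' thresholds (10 uM / 50 percent) for its true label.  Two kinds of
#' complication are planted with known ground truth:
#'
#' * with probability `conflict_rate`, a compound instead gets exactly 3
#'   same-type records, 2 agreeing with its label and 1 contradicting —
#'   a 2-of-3 split that the strict more-than-two-thirds rule must always
#'   exclude (`manifest$conflicted`);
#' * with probability 0.1, a compound gets 2 IC50 records supporting its
#'   label plus 2 percent-inhibition records contradicting it — resolvable
#'   only through IC50 priority (`manifest$ic50_priority_planted`; without
#'   priority the vote would be a 2-of-4 tie).
#'
#' @param spec A [synth_spec()].
#' @param labels Binary 0/1 true labels.
#' @param compound_keys Optional keys; default `SYN000001...`.
#' @return List: `records` (data.frame with columns `compound_key`,
#'   `source`, `reference`, `measurement_type`, `value`) and `manifest`
#'   (`true_label`, `conflicted`, `ic50_priority_planted`).
#' @export
gen_assay_records <- function(spec, labels, compound_keys = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  keys <- compound_keys %||% sprintf("SYN%06d", seq_along(labels))
  with_seed(derive_seed(spec$seed, "assay"), {
    sources <- c("chembl_like", "gostar_like", "hts_like", "central_like")
    sample_value <- function(type, lab) {
      if (type == "IC50") {
        if (lab == 1) runif(1, 0.01, 10) else runif(1, 10.5, 500)
      } else {
        if (lab == 1) runif(1, 50, 100) else runif(1, 0, 49.5)
      }
    }
    rows <- vector("list", length(labels))
    conflicted <- logical(length(labels))
    priority <- logical(length(labels))
    for (i in seq_along(labels)) {
      u <- runif(1)
      if (u < spec$conflict_rate) {
        conflicted[i] <- TRUE
        t <- sample(c("IC50", "percent_inhibition"), 1)
        types <- rep(t, 3)
        vals <- c(sample_value(t, labels[i]), sample_value(t, labels[i]),
                  sample_value(t, 1 - labels[i]))
      } else if (u < spec$conflict_rate + 0.1) {
        priority[i] <- TRUE
        types <- c("IC50", "IC50", "percent_inhibition",
                   "percent_inhibition")
        vals <- c(sample_value("IC50", labels[i]),
                  sample_value("IC50", labels[i]),
                  sample_value("percent_inhibition", 1 - labels[i]),
                  sample_value("percent_inhibition", 1 - labels[i]))
      } else {
        n_rec <- sample.int(4, 1)
        types <- sample(c("IC50", "percent_inhibition"), n_rec,
                        replace = TRUE)
        vals <- vapply(types, sample_value, 0, lab = labels[i])
      }
      rows[[i]] <- data.frame(
        compound_key = keys[i],
        source = sample(sources, length(vals), replace = TRUE),
        reference = sprintf("ref_%06d_%d", i, seq_along(vals)),
        measurement_type = types,
        value = vals,
        stringsAsFactors = FALSE)
    }
    list(records = do.call(rbind, rows),
         manifest = list(compound_key = keys, true_label = labels,
                         conflicted = conflicted,
                         ic50_priority_planted = priority))
  })
}
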