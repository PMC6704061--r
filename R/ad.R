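#' Applicability-domain report from max-similarity values
#'
#' Quantifies prediction reliability as a function of each query
#' compound's maximum Tanimoto similarity to the training set.  Queries
#' are binned into similarity intervals of width `bin_width`
#' (left-closed, right-open, the last bin closed: `[0,0.1), ...,
#' [0.9,1]`) and split into *inside* (`similarity >= threshold`) and
#' *outside* (`< threshold`) the applicability domain; classification
#' statistics are reported per bin and per partition.  A bin lacking a
#' class reports the affected statistics as `NA`.
#'
#' @param similarities Max Tanimoto similarity per query, in `[0, 1]`
#'   (from [max_similarities()]).
#' @param predictions Binary 0/1 predicted labels.
#' @param truths Binary 0/1 observed labels.
#' @param threshold Inside/outside similarity cutoff, default 0.6.
#' @param bin_width Similarity bin width, default 0.1.
#' @return Object of class `ad_report`: `bins` (data.frame with bin
#'   edges, class counts, confusion counts and statistics), `inside` and
#'   `outside` (each a list with `n`, `cm`, `metrics`), `global` metrics,
#'   `threshold`.
#' @export
ad_report <- function(similarities, predictions, truths, threshold = 0.6,
                      bin_width = 0.1) {
  n <- length(similarities)
  if (length(predictions) != n || length(truths) != n)
    stop_data("similarities, predictions, truths must have equal length")
  if (threshold < 0 || threshold > 1)
    stop_data("threshold must be in [0, 1]")
  if (any(similarities < 0 | similarities > 1))
    stop_data("similarities must be in [0, 1]")

  edges <- seq(0, 1, by = bin_width)
  nb <- length(edges) - 1L
  # left-closed bins; the last bin also contains similarity == 1.
  # round before floor so 0.6/0.1 = 5.999... lands in [0.6, 0.7)
  bin_of <- pmin(floor(round(similarities / bin_width, 9)) + 1L, nb)

  cm_stats <- function(idx) {
    if (!length(idx))
      return(list(cm = NULL, metrics = NULL, n = 0L))
    cm <- confusion_counts(truths[idx], predictions[idx])
    list(cm = cm, metrics = classification_metrics(cm), n = length(idx))
  }

  bins <- do.call(rbind, lapply(seq_len(nb), function(b) {
    idx <- which(bin_of == b)
    s <- cm_stats(idx)
    met <- s$metrics
    data.frame(
      lower = edges[b], upper = edges[b + 1L], n = s$n,
      n_pos = sum(truths[idx] == 1), n_neg = sum(truths[idx] == 0),
      tp = s$cm$tp %||% 0L, fn = s$cm$fn %||% 0L,
      fp = s$cm$fp %||% 0L, tn = s$cm$tn %||% 0L,
      accuracy = met$accuracy %||% NA_real_,
      sensitivity = met$sensitivity %||% NA_real_,
      specificity = met$specificity %||% NA_real_,
      balanced_accuracy = met$balanced_accuracy %||% NA_real_,
      kappa = met$kappa %||% NA_real_)
  }))

  inside <- cm_stats(which(similarities >= threshold))
  outside <- cm_stats(which(similarities < threshold))
  global <- cm_stats(seq_len(n))
  structure(list(bins = bins, inside = inside, outside = outside,
                 global = global, threshold = threshold,
                 bin_width = bin_width,
                 median_similarity = stats::median(similarities)),
            class = "ad_report")
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf(
    "applicability domain (threshold %.2f): %d inside / %d outside, median sim %.3f\n",
    x$threshold, x$inside$n, x$outside$n, x$median_similarity))
  if (!is.null(x$inside$metrics))
    cat("  inside : ", format(x$inside$metrics), "\n", sep = "")
  if (!is.null(x$outside$metrics))
    cat("  outside: ", format(x$outside$metrics), "\n", sep = "")
  invisible(x)
}
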