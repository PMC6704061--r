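#' Activity class of a single assay record
#'
#' Applies the binary activity thresholds: an IC50 at or below
#' `ic50_threshold` (micromolar), or a percent inhibition at 10 uM at or
#' above `inhibition_threshold`, labels a record `"inhibitor"`; otherwise
#' `"inactive"`.  Both boundaries are inclusive on the inhibitor side.
#'
#' @param measurement_type `"IC50"` or `"percent_inhibition"`.
#' @param value Numeric measurement (uM for IC50, percent for inhibition).
#' @param ic50_threshold IC50 cutoff in uM, default 10.
#' @param inhibition_threshold Percent-inhibition cutoff, default 50.
#' @return `"inhibitor"` or `"inactive"`.
#' @examples
#' label_record("IC50", 5)                 # inhibitor
#' label_record("percent_inhibition", 49.9) # inactive
#' @export
label_record <- function(measurement_type, value,
                         ic50_threshold = 10, inhibition_threshold = 50) {
  if (length(measurement_type) != 1 || length(value) != 1)
    stop_data("label_record labels one record at a time")
  if (!measurement_type %in% c("IC50", "percent_inhibition"))
    stop_data("unknown measurement_type: ", measurement_type)
  if (!is.finite(value))
    stop_data("rejected record: non-finite value")
  if (measurement_type == "IC50") {
    if (value <= 0) stop_data("rejected record: non-positive IC50")
    if (value <= ic50_threshold) "inhibitor" else "inactive"
  } else {
    if (value >= inhibition_threshold) "inhibitor" else "inactive"
  }
}

# Vectorised internal version; returns character vector, NA for invalid
# records (which callers report as rejected).
label_records_vec <- function(measurement_type, value,
                              ic50_threshold = 10, inhibition_threshold = 50) {
  out <- rep(NA_character_, length(value))
  ok <- is.finite(value) &
    measurement_type %in% c("IC50", "percent_inhibition")
  ic <- ok & measurement_type == "IC50"
  ok[ic & value <= 0] <- FALSE
  ic <- ic & ok
  pi <- ok & measurement_type == "percent_inhibition"
  out[ic] <- ifelse(value[ic] <= ic50_threshold, "inhibitor", "inactive")
  out[pi] <- ifelse(value[pi] >= inhibition_threshold, "inhibitor",
                    "inactive")
  out
}

#' Resolve one compound's assay reports to a single label
#'
#' When IC50 reports exist for a compound they take priority and
#' percent-inhibition reports are ignored entirely.  Each voting report
#' contributes its per-record class; the compound is assigned the majority
#' class only when its vote fraction is *strictly* greater than
#' `agreement` (default 2/3), otherwise the compound is `"excluded"` as
#' contradictory.
#'
#' @param records data.frame with columns `measurement_type` and `value`
#'   (all rows for one compound).
#' @param agreement Strict lower bound on the winning vote fraction.
#' @param ic50_threshold,inhibition_threshold Passed to [label_record()].
#' @return List with `label` (`"inhibitor"`, `"inactive"` or
#'   `"excluded"`), `n_reports`, `n_voting` and `agreement_fraction`.
#' @examples
#' recs <- data.frame(measurement_type = c("IC50", "IC50",
#'                                         "percent_inhibition"),
#'                    value = c(2, 4, 10))
#' resolve_compound(recs)$label  # IC50 records outvote the %-inhibition one
#' @export
resolve_compound <- function(records, agreement = 2 / 3,
                             ic50_threshold = 10,
                             inhibition_threshold = 50) {
  if (is.null(records) || nrow(records) == 0)
    stop_data("resolve_compound: no records")
  labs <- label_records_vec(records$measurement_type, records$value,
                            ic50_threshold, inhibition_threshold)
  labs <- labs[!is.na(labs)]
  if (length(labs) == 0) stop_data("resolve_compound: no valid records")
  has_ic50 <- any(records$measurement_type == "IC50" &
                    is.finite(records$value) & records$value > 0)
  if (has_ic50) {
    voting <- label_records_vec(
      records$measurement_type[records$measurement_type == "IC50"],
      records$value[records$measurement_type == "IC50"],
      ic50_threshold, inhibition_threshold)
    voting <- voting[!is.na(voting)]
  } else voting <- labs
  tab <- table(factor(voting, levels = c("inhibitor", "inactive")))
  frac <- max(tab) / length(voting)
  winner <- names(tab)[which.max(tab)]
  label <- if (frac > agreement) winner else "excluded"
  list(label = label, n_reports = nrow(records),
       n_voting = length(voting), agreement_fraction = unname(frac))
}

#' Integrate assay record tables into a labeled compound table
#'
#' Concatenates per-source record tables, collapses exact duplicates
#' (identical `compound_key`, `reference`, `measurement_type`, `value`),
#' and resolves each compound with [resolve_compound()].  Invalid records
#' (non-finite values, non-positive IC50s, unknown measurement types,
#' missing units when a `units` column is present) are rejected and
#' counted, never guessed.
#'
#' @param sources A data.frame or list of data.frames with columns
#'   `compound_key`, `source`, `measurement_type`, `value` and optionally
#'   `reference`, `units`.
#' @param agreement,ic50_threshold,inhibition_threshold Curation
#'   parameters, see [resolve_compound()].
#' @return List of class `curation_result`: `labels` (data.frame
#'   `compound_key`, `label`, `n_reports`, `agreement_fraction`, sorted by
#'   key) and `report` (per-source counts, duplicates removed, rejected
#'   records, label counts).
#' @export
integrate_assays <- function(sources, agreement = 2 / 3,
                             ic50_threshold = 10,
                             inhibition_threshold = 50) {
  if (is.data.frame(sources)) sources <- list(sources)
  req <- c("compound_key", "source", "measurement_type", "value")
  for (s in sources) {
    miss <- setdiff(req, names(s))
    if (length(miss))
      stop_data("assay table missing required column(s): ",
                paste(miss, collapse = ", "))
  }
  rec <- do.call(rbind, lapply(sources, function(s) {
    data.frame(compound_key = as.character(s$compound_key),
               source = as.character(s$source),
               reference = if ("reference" %in% names(s))
                 as.character(s$reference) else NA_character_,
               measurement_type = as.character(s$measurement_type),
               value = as.numeric(s$value),
               units = if ("units" %in% names(s))
                 as.character(s$units) else NA_character_,
               has_units_col = "units" %in% names(s),
               stringsAsFactors = FALSE)
  }))
  n_in <- nrow(rec)
  per_source_in <- table(rec$source)

  # reject: missing units where a units column was supplied, bad values
  bad_units <- rec$has_units_col & (is.na(rec$units) | rec$units == "")
  bad_value <- is.na(label_records_vec(rec$measurement_type, rec$value,
                                       ic50_threshold,
                                       inhibition_threshold))
  rejected <- bad_units | bad_value
  rec <- rec[!rejected, , drop = FALSE]

  # collapse exact duplicates across sources
  dup_key <- paste(rec$compound_key, rec$reference, rec$measurement_type,
                   format(rec$value, digits = 15), sep = "\r")
  dup <- duplicated(dup_key)
  n_dup <- sum(dup)
  rec <- rec[!dup, , drop = FALSE]

  keys <- sort(unique(rec$compound_key))
  idx <- split(seq_len(nrow(rec)), rec$compound_key)
  res <- lapply(keys, function(k)
    resolve_compound(rec[idx[[k]], , drop = FALSE], agreement,
                     ic50_threshold, inhibition_threshold))
  labels <- data.frame(
    compound_key = keys,
    label = vapply(res, `[[`, "", "label"),
    n_reports = vapply(res, `[[`, 0L, "n_reports"),
    agreement_fraction = vapply(res, `[[`, 0, "agreement_fraction"),
    stringsAsFactors = FALSE)
  report <- list(
    records_in = n_in,
    records_per_source = as.list(per_source_in),
    records_rejected = sum(rejected),
    duplicates_removed = n_dup,
    compounds = length(keys),
    label_counts = as.list(table(factor(labels$label,
      levels = c("inhibitor", "inactive", "excluded")))),
    parameters = list(agreement = agreement,
                      ic50_threshold = ic50_threshold,
                      inhibition_threshold = inhibition_threshold))
  structure(list(labels = labels, report = report),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "curation: %d records -> %d compounds (%d dup removed, %d rejected)\n",
    r$records_in, r$compounds, r$duplicates_removed, r$records_rejected))
  cat(sprintf("  inhibitor %d / inactive %d / excluded %d\n",
              r$label_counts$inhibitor, r$label_counts$inactive,
              r$label_counts$excluded))
  invisible(x)
}

#' Stratified train/test split
#'
#' Random split stratified by label: each class contributes
#' `floor(n_class * test_fraction)` compounds to the test set, the
#' remainder to the training set.  Reproducible under `seed`.
#'
#' @param labels data.frame with columns `compound_key` and `label`
#'   (excluded compounds, if present, must be dropped beforehand).
#' @param test_fraction Test proportion in (0, 1); default 0.3.
#' @param seed Integer seed.
#' @return List with data.frames `train` and `test`.
#' @export
split_train_test <- function(labels, test_fraction = 0.3, seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_data("test_fraction must be in (0, 1)")
  if (any(labels$label == "excluded"))
    stop_data("drop excluded compounds before splitting")
  classes <- unique(labels$label)
  sizes <- table(labels$label)
  if (any(sizes < 2))
    stop_data("each class needs at least 2 members to split")
  test_idx <- with_seed(derive_seed(seed, "split"), {
    unlist(lapply(classes, function(cl) {
      i <- which(labels$label == cl)
      sample(i, floor(length(i) * test_fraction))
    }))
  })
  list(train = labels[-test_idx, , drop = FALSE],
       test = labels[test_idx, , drop = FALSE])
}
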