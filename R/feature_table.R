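#' Construct a feature table
#'
#' A compound-by-descriptor numeric matrix with named columns, row keys,
#' and an audit trail (`dropped_log`) recording every column removed by
#' filtering together with the stage and reason.
#'
#' @param x Numeric matrix or data.frame of descriptors (columns named).
#' @param compound_keys Optional character row keys; default taken from
#'   rownames or generated.
#' @return Object of class `feature_table` with elements `values` (matrix),
#'   `compound_keys`, `descriptors`, `dropped_log` (data.frame with
#'   columns `column`, `stage`, `reason`, `partner`).
#' @export
feature_table <- function(x, compound_keys = NULL) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop_data("descriptor values must be numeric")
  if (is.null(colnames(m)))
    stop_data("descriptor columns must be named")
  if (anyDuplicated(colnames(m)))
    stop_data("duplicated descriptor names: ",
              paste(unique(colnames(m)[duplicated(colnames(m))]),
                    collapse = ", "))
  keys <- compound_keys %||% rownames(m) %||%
    sprintf("cmpd_%05d", seq_len(nrow(m)))
  if (length(keys) != nrow(m))
    stop_data("compound_keys length does not match row count")
  rownames(m) <- keys
  structure(list(values = m, compound_keys = keys,
                 descriptors = colnames(m),
                 dropped_log = empty_dropped_log()),
            class = "feature_table")
}

empty_dropped_log <- function() {
  data.frame(column = character(), stage = character(),
             reason = character(), partner = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d compounds x %d descriptors (%d dropped)\n",
              nrow(x$values), ncol(x$values), nrow(x$dropped_log)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Blacklist, zero-variance, and correlation filtering of descriptors
#'
#' Three sequential stages: (1) remove blacklisted columns; (2) remove
#' columns with zero variance; (3) greedy pairwise correlation pruning:
#' column pairs are visited in input column order and whenever a pair's
#' correlation exceeds `corr_threshold`, the later column is dropped (the
#' partner is recorded in the audit log).  By default the absolute Pearson
#' correlation is used so strong anti-correlation also counts as
#' redundancy; set `use_abs = FALSE` for the signed coefficient.
#'
#' @param ft A `feature_table`.
#' @param blacklist Character vector of column names to remove first.
#' @param corr_threshold Correlation threshold in (0, 1]; default 0.85.
#' @param use_abs Use `|r|` (default) rather than signed `r`.
#' @return Filtered `feature_table` with an appended `dropped_log`.
#' @export
filter_descriptors <- function(ft, blacklist = character(),
                               corr_threshold = 0.85, use_abs = TRUE) {
  stopifnot(inherits(ft, "feature_table"))
  if (corr_threshold <= 0 || corr_threshold > 1)
    stop_data("corr_threshold must be in (0, 1]")
  m <- ft$values
  log <- ft$dropped_log

  bl <- intersect(blacklist, colnames(m))
  if (length(bl)) {
    log <- rbind(log, data.frame(column = bl, stage = "blacklist",
                                 reason = "blacklisted",
                                 partner = NA_character_))
    m <- m[, setdiff(colnames(m), bl), drop = FALSE]
  }

  if (ncol(m)) {
    v <- apply(m, 2, var)
    zv <- colnames(m)[v == 0 | is.na(v)]
    if (length(zv)) {
      log <- rbind(log, data.frame(column = zv, stage = "variance",
                                   reason = "zero variance",
                                   partner = NA_character_))
      m <- m[, setdiff(colnames(m), zv), drop = FALSE]
    }
  }

  if (ncol(m) > 1) {
    r <- cor(m)
    if (use_abs) r <- abs(r)
    keep <- rep(TRUE, ncol(m))
    for (i in seq_len(ncol(m) - 1)) {
      if (!keep[i]) next
      for (j in seq(i + 1, ncol(m))) {
        if (keep[j] && !is.na(r[i, j]) && r[i, j] > corr_threshold) {
          keep[j] <- FALSE
          log <- rbind(log, data.frame(
            column = colnames(m)[j], stage = "correlation",
            reason = sprintf("r=%.3f with %s", r[i, j], colnames(m)[i]),
            partner = colnames(m)[i]))
        }
      }
    }
    m <- m[, keep, drop = FALSE]
  }

  if (ncol(m) == 0) stop_data("no descriptors survive filtering")
  out <- ft
  out$values <- m
  out$descriptors <- colnames(m)
  out$dropped_log <- log
  out
}
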