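#' Read a descriptor table from delimited text
#'
#' Delimiter (comma/tab/semicolon) is autodetected.  The first column is
#' taken as the compound key when named `compound_key` (or when it is
#' non-numeric); all remaining columns must be numeric.
#'
#' @param path File path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  dt <- data.table::fread(path, data.table = FALSE)
  if (!ncol(dt)) stop_data("empty table: ", path)
  keycol <- if (names(dt)[1] == "compound_key" || !is.numeric(dt[[1]]))
    1L else 0L
  keys <- if (keycol) as.character(dt[[1]]) else NULL
  vals <- if (keycol) dt[-1] else dt
  bad <- names(vals)[!vapply(vals, is.numeric, TRUE)]
  if (length(bad))
    stop_data("non-numeric descriptor column(s): ",
              paste(bad, collapse = ", "))
  feature_table(as.matrix(vals), keys)
}

#' Write a feature table as delimited text
#'
#' @param ft A `feature_table`.
#' @param path Output path.
#' @param sep Delimiter, default comma.
#' @export
write_feature_table <- function(ft, path, sep = ",") {
  df <- data.frame(compound_key = ft$compound_keys, ft$values,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

#' Read assay records from delimited text
#'
#' Requires columns `compound_key`, `source`, `measurement_type`,
#' `value`; `reference` and `units` are optional.
#'
#' @param path File path (delimiter autodetected).
#' @return data.frame of assay records.
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  dt <- data.table::fread(path, data.table = FALSE)
  req <- c("compound_key", "source", "measurement_type", "value")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop_data("assay table ", path, " missing column(s): ",
              paste(miss, collapse = ", "))
  dt
}

#' Read fingerprints from delimited text
#'
#' Expects a column `fingerprint` (plus optional `compound_key`).
#'
#' @param path File path.
#' @param dialect Fingerprint string dialect, see [parse_fingerprints()].
#' @param width Optional declared bit width.
#' @return A [fingerprint_set()].
#' @export
read_fingerprints <- function(path, dialect = "bits", width = NULL) {
  dt <- data.table::fread(path, data.table = FALSE,
                          colClasses = list(character = "fingerprint"))
  if (!"fingerprint" %in% names(dt))
    stop_data("fingerprint table needs a 'fingerprint' column")
  parse_fingerprints(as.character(dt$fingerprint), dialect, width)
}

#' Write fingerprints as delimited text
#'
#' @param fps A `fingerprint_set`.
#' @param path Output path.
#' @param dialect Output dialect.
#' @param compound_keys Optional key column.
#' @export
write_fingerprints <- function(fps, path, dialect = "indices",
                               compound_keys = NULL) {
  df <- data.frame(
    compound_key = compound_keys %||%
      sprintf("cmpd_%05d", seq_along(fps$bits)),
    fingerprint = format_fingerprints(fps, dialect))
  data.table::fwrite(df, path)
  invisible(path)
}

#' Serialize a curation/selection report to JSON
#'
#' Every report embeds the resolved parameters and their hash so equal
#' configurations are recognizably equal across runs.
#'
#' @param x List to serialize.
#' @param path Output path.
#' @export
write_report_json <- function(x, path) {
  x$config_hash <- config_hash(x$parameters %||% x$config %||% list())
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

# stable short hash of a resolved configuration list
config_hash <- function(cfg) {
  if (length(cfg) && !is.null(names(cfg)))
    cfg <- cfg[order(names(cfg))]
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  v <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(v * (seq_along(v) %% 251)) %% .Machine$integer.max)
}

#' Serialize an NSGA-II archive to JSON
#'
#' Masks are stored as 1-based on-index lists; the per-generation fronts
#' and the dominance-ratio series are both included.
#'
#' @param result An `nsga2_result`.
#' @param path Output path.
#' @export
write_archive_json <- function(result, path) {
  arch <- lapply(seq_along(result$archive), function(g) {
    fr <- result$archive[[g]]
    list(generation = g,
         solutions = lapply(seq_along(fr$kappa), function(i)
           list(on = which(fr$masks[[i]]), kappa = fr$kappa[i],
                n = fr$n[i])))
  })
  out <- list(config = unclass(result$config),
              dominance_ratios = result$dominance_ratios,
              cache_stats = result$cache_stats[c("evaluations",
                                                 "cache_hits")],
              generations = arch)
  write_report_json(out, path)
}
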