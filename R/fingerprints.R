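#' Binary structural fingerprints as on-bit sets
#'
#' A fingerprint is stored as a sorted integer vector of "on" bit indices
#' (0-based), the sparse representation natural for circular fingerprints
#' such as ECFP_4 whose bit space is wide but sparsely populated.  A
#' `fingerprint_set` is a list of such vectors with a common optional bit
#' width.
#'
#' @param on_bits List (one element per compound) of non-negative integer
#'   vectors of on-bit indices.
#' @param width Optional total bit-space width; when given, all indices
#'   must be `< width`.
#' @return Object of class `fingerprint_set`.
#' @export
fingerprint_set <- function(on_bits, width = NULL) {
  on_bits <- lapply(on_bits, function(b) {
    b <- sort(unique(as.integer(b)))
    if (length(b) && b[1] < 0) stop_data("negative bit index")
    if (!is.null(width) && length(b) && max(b) >= width)
      stop_data("bit index >= declared width ", width)
    b
  })
  structure(list(bits = on_bits, width = width), class = "fingerprint_set")
}

#' @export
length.fingerprint_set <- function(x) length(x$bits)

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(sprintf("fingerprint_set: %d fingerprints%s, mean %.1f on-bits\n",
              length(x$bits),
              if (is.null(x$width)) "" else sprintf(" (width %d)", x$width),
              mean(lengths(x$bits))))
  invisible(x)
}

#' @export
`[.fingerprint_set` <- function(x, i) fingerprint_set(x$bits[i], x$width)

#' Parse fingerprint strings in one of three dialects
#'
#' @param strings Character vector, one fingerprint per element.
#' @param dialect `"bits"` (string of 0/1 characters, bit 0 leftmost),
#'   `"hex"` (hexadecimal, MSB-first within each 4-bit nibble block, the
#'   whole string read as a big bit field with bit 0 the most significant
#'   bit of the first hex digit), or `"indices"` (semicolon-separated
#'   0-based on-bit indices, empty string = empty fingerprint).
#' @param width Optional declared width (inferred for `"bits"`/`"hex"`).
#' @return A `fingerprint_set`.
#' @export
parse_fingerprints <- function(strings,
                               dialect = c("bits", "hex", "indices"),
                               width = NULL) {
  dialect <- match.arg(dialect)
  bits <- switch(dialect,
    bits = {
      if (is.null(width) && length(strings)) width <- nchar(strings[1])
      lapply(seq_along(strings), function(i) {
        s <- strings[i]
        if (grepl("[^01]", s))
          stop_data("row ", i, ": bitstring contains non-0/1 characters")
        which(strsplit(s, "")[[1]] == "1") - 1L
      })
    },
    hex = {
      if (is.null(width) && length(strings))
        width <- 4L * nchar(strings[1])
      lapply(seq_along(strings), function(i) {
        s <- toupper(strings[i])
        if (grepl("[^0-9A-F]", s))
          stop_data("row ", i, ": invalid hex fingerprint")
        nib <- strtoi(strsplit(s, "")[[1]], 16L)
        on <- integer(0)
        for (k in seq_along(nib)) {
          v <- nib[k]
          # MSB of the nibble is the lowest bit index of its block
          on <- c(on, (k - 1L) * 4L + which(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0) - 1L)
        }
        on
      })
    },
    indices = lapply(seq_along(strings), function(i) {
      s <- trimws(strings[i])
      if (s == "") return(integer(0))
      v <- suppressWarnings(as.integer(strsplit(s, ";")[[1]]))
      if (anyNA(v)) stop_data("row ", i, ": malformed on-bit index list")
      v
    })
  )
  fingerprint_set(bits, width)
}

#' Format a fingerprint set as strings
#'
#' Inverse of [parse_fingerprints()].
#' @param fps A `fingerprint_set`.
#' @param dialect Output dialect; `"hex"` requires a width that is a
#'   multiple of 4, `"bits"` requires a declared width.
#' @return Character vector.
#' @export
format_fingerprints <- function(fps, dialect = c("bits", "hex", "indices")) {
  dialect <- match.arg(dialect)
  if (dialect == "indices")
    return(vapply(fps$bits, paste, "", collapse = ";"))
  w <- fps$width
  if (is.null(w)) stop_data("bits/hex output needs a declared width")
  vapply(fps$bits, function(b) {
    v <- integer(w); v[b + 1L] <- 1L
    if (dialect == "bits") return(paste(v, collapse = ""))
    nib <- matrix(v, nrow = 4)
    paste(sprintf("%X", colSums(nib * c(8L, 4L, 2L, 1L))), collapse = "")
  }, "")
}

#' Tanimoto (Jaccard) similarity of two fingerprints
#'
#' `|A n B| / |A u B|` over on-bit sets.  Two empty fingerprints have, by
#' convention, similarity `empty_value` (default 0: an empty fingerprint
#' carries no evidence of similarity; set 1 to treat them as identical).
#'
#' @param a,b Integer vectors of on-bit indices.
#' @param empty_value Similarity assigned when both sets are empty.
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 2, 3), c(2, 3, 4))  # 0.5
#' @export
tanimoto <- function(a, b, empty_value = 0) {
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  u <- length(union(a, b))
  if (u == 0) return(empty_value)
  length(intersect(a, b)) / u
}

# Dense 0/1 matrix (compounds x bits) from a fingerprint_set, for
# bulk similarity computation and for use as SVM input columns.
fp_matrix <- function(fps, width = NULL) {
  w <- width %||% fps$width %||%
    (max(c(0L, unlist(fps$bits))) + 1L)
  m <- matrix(0, nrow = length(fps$bits), ncol = w)
  for (i in seq_along(fps$bits))
    if (length(fps$bits[[i]])) m[i, fps$bits[[i]] + 1L] <- 1
  colnames(m) <- sprintf("bit_%04d", seq_len(w) - 1L)
  m
}

# All-pairs Tanimoto similarity between two fingerprint sets (rows of the
# result index `query`, columns index `ref`).  Dense matrix algebra:
# intersection = A B^T; union = |a| + |b| - intersection.
tanimoto_cross <- function(query, ref, empty_value = 0) {
  w <- max(query$width %||% 0L, ref$width %||% 0L,
           max(c(0L, unlist(query$bits), unlist(ref$bits))) + 1L)
  qa <- fp_matrix(query, w); rb <- fp_matrix(ref, w)
  inter <- qa %*% t(rb)
  un <- outer(rowSums(qa), rowSums(rb), `+`) - inter
  s <- ifelse(un == 0, empty_value, inter / pmax(un, 1e-300))
  s
}

#' Maximum Tanimoto similarity of a query to a training set
#'
#' Exact linear scan over all training fingerprints; ties resolved to the
#' lowest training index.
#'
#' @param query Integer vector of on-bit indices (one query compound).
#' @param training A `fingerprint_set` (non-empty).
#' @param empty_value See [tanimoto()].
#' @return List with `similarity` and `index` (argmax into `training`).
#' @export
max_sim_to_train <- function(query, training, empty_value = 0) {
  if (length(training$bits) == 0) stop_data("empty training set")
  sims <- vapply(training$bits, tanimoto, 0, a = query,
                 empty_value = empty_value)
  i <- which.max(sims)
  list(similarity = sims[i], index = i)
}

#' Per-query maximum similarity to a training set
#'
#' Vectorised version of [max_sim_to_train()] over a whole query set.
#'
#' @param query,training `fingerprint_set`s.
#' @param empty_value See [tanimoto()].
#' @return Numeric vector of max similarities, one per query compound.
#' @export
max_similarities <- function(query, training, empty_value = 0) {
  if (length(training$bits) == 0) stop_data("empty training set")
  s <- tanimoto_cross(query, training, empty_value)
  apply(s, 1, max)
}

#' Trim the majority class by fingerprint clustering
#'
#' Partitions the given fingerprints into `n_clusters` clusters under
#' Tanimoto distance and returns one representative per cluster, mirroring
#' the strategy of balancing a grossly imbalanced training set by keeping
#' one inactive per cluster.  Cluster seeds are chosen by max-min
#' (farthest-point) sphere exclusion starting from a random compound;
#' every compound is assigned to its nearest seed and each cluster is then
#' refined to its medoid (member minimizing total within-cluster Tanimoto
#' distance).  Deterministic under `seed`.
#'
#' @param fps `fingerprint_set` of the majority-class compounds.
#' @param n_clusters Number of representatives wanted (`<= length(fps)`).
#' @param seed Integer seed.
#' @return Integer vector of `n_clusters` representative indices into
#'   `fps`, sorted increasing.
#' @export
trim_majority_by_clustering <- function(fps, n_clusters, seed = 1) {
  n <- length(fps$bits)
  if (n_clusters <= 0) stop_data("n_clusters must be positive")
  if (n_clusters > n)
    stop_data("n_clusters exceeds number of compounds")
  if (n_clusters == n) return(seq_len(n))
  d <- 1 - tanimoto_cross(fps, fps)
  start <- with_seed(derive_seed(seed, "trim"), sample.int(n, 1))
  seeds <- integer(n_clusters)
  seeds[1] <- start
  mind <- d[, start]
  if (n_clusters > 1) for (k in 2:n_clusters) {
    seeds[k] <- which.max(mind)   # ties -> lowest index, deterministic
    mind <- pmin(mind, d[, seeds[k]])
  }
  assign <- apply(d[, seeds, drop = FALSE], 1, which.min)
  reps <- vapply(seq_len(n_clusters), function(k) {
    members <- which(assign == k)
    if (!length(members)) return(seeds[k])  # duplicate-seed edge case
    members[which.min(rowSums(d[members, members, drop = FALSE]))]
  }, 0L)
  sort(reps)
}
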