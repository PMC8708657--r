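# All featurizers share the FeatureMatrix container: a numeric matrix of
# instances x features with species labels and the scheme parameters kept
# alongside, ready for cross-validated classification.

new_feature_matrix <- function(values, instance_ids, labels, feature_names,
                               scheme, params = list()) {
  dimnames(values) <- list(instance_ids, feature_names)
  structure(list(values = values, instance_ids = instance_ids,
                 labels = labels, feature_names = feature_names,
                 scheme = scheme, params = params),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix [%s]: %d instances x %d features (%s)\n",
              x$scheme, nrow(x$values), ncol(x$values),
              paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

# Lexicographic names of {A,C,G,T}^k, in the index order used by the
# counting code (first letter most significant).
kmer_names <- function(k) {
  grid <- expand.grid(rep(list(.BASES), k))[, k:1, drop = FALSE]
  do.call(paste0, grid)
}

# Index of each valid window of `codes` (1..4^k), NA where the window
# touches a non-ACGT position.
.window_index <- function(codes, k) {
  L <- length(codes)
  if (L < k) return(integer(0))
  E <- utils::head(embed(codes, k)[, k:1, drop = FALSE], L - k + 1L)
  idx <- as.vector((E - 1L) %*% 4L^((k - 1L):0L)) + 1L
  idx[rowSums(is.na(E)) == 0L]
}

.strip_gaps <- function(sequence) gsub("-", "", sequence, fixed = TRUE)

# Raw spectrum counts (length 4^k) for one sequence string.
.spectrum_counts <- function(sequence, k) {
  codes <- encode_codes(.strip_gaps(sequence))
  w <- .window_index(codes, k)
  as.numeric(tabulate(w, nbins = 4L^k))
}

.normalize_rows <- function(m, raw) {
  if (raw) return(m)
  s <- rowSums(m)
  s[s == 0] <- 1
  m / s
}

.featurize <- function(ds, counter, scheme, k, params, raw) {
  rows <- lapply(ds$records$sequence, counter)
  short <- vapply(rows, function(r) sum(r) == 0, logical(1)) &
    nchar(.strip_gaps(ds$records$sequence)) < k
  if (any(short))
    warning(sum(short), " sequence(s) shorter than k after gap ",
            "stripping: all-zero feature row(s)")
  values <- .normalize_rows(do.call(rbind, rows), raw)
  new_feature_matrix(values, ds$records$record_id, ds$records$species,
                     kmer_names(k), scheme, params)
}

#' Numeric per-column encoding of an aligned dataset
#'
#' Each alignment column becomes one feature with the fixed code
#' `A=1, C=2, G=3, T=4`, gap/other `=0`.
#'
#' @param ds an aligned `BarcodeDataset`.
#' @return A `FeatureMatrix` with `scheme = "aligned-columns"`.
#' @export
encode_alignment <- function(ds) {
  if (!ds$aligned) stop("encode_alignment requires an aligned dataset")
  L <- nchar(ds$records$sequence[1])
  values <- t(vapply(ds$records$sequence, function(s) {
    v <- encode_codes(s)
    v[is.na(v)] <- 0L
    as.numeric(v)
  }, numeric(L)))
  new_feature_matrix(values, ds$records$record_id, ds$records$species,
                     sprintf("pos%04d", seq_len(L)), "aligned-columns")
}

#' k-mer spectrum features
#'
#' Counts of every contiguous k-mer over `{A,C,G,T}`; gaps are stripped
#' first and windows containing any other symbol are skipped. By default
#' counts are normalised to relative frequencies per sequence (each row
#' divided by its number of counted windows); `raw = TRUE` keeps counts.
#'
#' @param ds a `BarcodeDataset`.
#' @param k k-mer length.
#' @param raw keep raw counts instead of relative frequencies.
#' @return A `FeatureMatrix` with `4^k` columns in lexicographic order.
#' @export
spectrum_features <- function(ds, k, raw = FALSE) {
  stopifnot(k >= 1)
  .featurize(ds, function(s) .spectrum_counts(s, k),
             "spectrum", k, list(k = k), raw)
}

# Offset patterns for the gappy kernel: all strictly increasing k-tuples
# of positions with total span <= k-1+g, expressed as offsets from the
# first position. Enumerated by distributing up to g extra gaps over the
# k-1 inter-position intervals.
.gappy_offsets <- function(k, g) {
  if (k == 1L) return(list(0L))
  extras <- expand.grid(rep(list(0:g), k - 1L))
  extras <- extras[rowSums(extras) <= g, , drop = FALSE]
  lapply(seq_len(nrow(extras)), function(r)
    c(0L, cumsum(1L + as.integer(extras[r, ]))))
}

.gappy_counts <- function(sequence, k, g) {
  codes <- encode_codes(.strip_gaps(sequence))
  L <- length(codes)
  counts <- numeric(4L^k)
  pow <- 4L^((k - 1L):0L)
  for (off in .gappy_offsets(k, g)) {
    span <- off[k] + 1L
    if (L < span) next
    starts <- seq_len(L - span + 1L)
    M <- vapply(off, function(o) codes[starts + o], integer(length(starts)))
    M <- matrix(M, ncol = k)
    ok <- rowSums(is.na(M)) == 0L
    if (!any(ok)) next
    idx <- as.vector((M[ok, , drop = FALSE] - 1L) %*% pow) + 1L
    counts <- counts + tabulate(idx, nbins = 4L^k)
  }
  counts
}

#' Gappy k-mer features
#'
#' `Phi_w(s)` counts the position tuples `i_1 < ... < i_k` with total span
#' `i_k - i_1 <= k-1+g` whose letters spell `w`: contiguous k-mers plus
#' k-mers with up to `g` internal gaps. `g = 0` collapses to the spectrum.
#' Positions with non-ACGT symbols are unusable.
#'
#' @inheritParams spectrum_features
#' @param g maximum number of internal gaps.
#' @return A `FeatureMatrix`.
#' @export
gappy_features <- function(ds, k, g = 1, raw = FALSE) {
  stopifnot(k >= 1, g >= 0)
  .featurize(ds, function(s) .gappy_counts(s, k, g),
             "gappy", k, list(k = k, g = g), raw)
}

# Hamming-ball sum over a spectrum-count vector: for every word w, the
# number of contiguous k-mer instances within Hamming distance <= m.
# Computed exactly via sum_{t<=m} sum_{|J|=t} prod_{j in J} D_j c with
# D_j = (sum over the letter at position j) - identity.
.hamming_ball_sum <- function(counts, k, m) {
  if (m == 0L) return(counts)
  a <- array(counts, dim = rep(4L, k))
  # counts index: first letter most significant => dim k varies fastest
  # (dim j of `a` corresponds to letter position k+1-j); symmetric ops only.
  sum_axis <- function(x, j) {
    perm <- c(j, setdiff(seq_len(k), j))
    xp <- aperm(x, perm)
    s <- colSums(matrix(xp, nrow = 4L))
    aperm(array(rep(s, each = 4L), dim = c(4L, dim(x)[perm][-1L])),
          order(perm))
  }
  res <- a
  for (t in seq_len(m)) {
    for (J in utils::combn(k, t, simplify = FALSE)) {
      b <- a
      for (j in J) b <- sum_axis(b, j) - b
      res <- res + b
    }
  }
  as.vector(res)
}

.mismatch_counts <- function(sequence, k, m) {
  .hamming_ball_sum(.spectrum_counts(sequence, k), k, m)
}

#' Mismatch k-mer features
#'
#' `Phi_w(s)` counts the contiguous k-mer instances of `s` lying within
#' Hamming distance `<= m` of `w`. `m = 0` collapses to the spectrum.
#'
#' @inheritParams spectrum_features
#' @param m maximum number of mismatches, `0 <= m < k`.
#' @return A `FeatureMatrix`.
#' @export
mismatch_features <- function(ds, k, m = 1, raw = FALSE) {
  stopifnot(k >= 1, m >= 0, m < k)
  .featurize(ds, function(s) .mismatch_counts(s, k, m),
             "mismatch", k, list(k = k, m = m), raw)
}

#' Write a feature matrix as labelled TSV
#'
#' First columns are `record_id` and `species`, then one column per
#' feature.
#'
#' @param fm a `FeatureMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(fm, path) {
  df <- data.frame(record_id = fm$instance_ids, species = fm$labels,
                   fm$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix in ARFF format
#'
#' Minimal attribute-relation file for interoperability with tabular
#' machine-learning tools: numeric attributes plus a nominal class.
#'
#' @inheritParams write_feature_tsv
#' @param relation relation name.
#' @return `path`, invisibly.
#' @export
write_feature_arff <- function(fm, path, relation = "barcodes") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("@RELATION %s", relation), con)
  for (f in fm$feature_names)
    writeLines(sprintf("@ATTRIBUTE %s NUMERIC", f), con)
  classes <- sort(unique(fm$labels))
  writeLines(sprintf("@ATTRIBUTE class {%s}",
                     paste(classes, collapse = ",")), con)
  writeLines("@DATA", con)
  rows <- apply(fm$values, 1L, function(r)
    paste(format(r, digits = 10, trim = TRUE, scientific = FALSE),
          collapse = ","))
  writeLines(paste(rows, fm$labels, sep = ","), con)
  invisible(path)
}
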