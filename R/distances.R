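#' Pairwise-deletion site bookkeeping for two aligned sequences
#'
#' Sites where either sequence carries a gap, `N` or any non-ACGT symbol
#' are excluded entirely (pairwise deletion). Transitions are the purine
#' and pyrimidine exchanges A<->G and C<->T; every other mismatch is a
#' transversion.
#'
#' @param a,b aligned nucleotide strings of equal length.
#' @return A list with `n` (comparable sites), `mismatches`, `transitions`
#'   and `transversions`; `mismatches == transitions + transversions`.
#' @export
comparable_sites <- function(a, b) {
  ca <- encode_codes(a)
  cb <- encode_codes(b)
  if (length(ca) != length(cb))
    stop("sequences must have equal (aligned) length")
  ok <- !is.na(ca) & !is.na(cb)
  ca <- ca[ok]; cb <- cb[ok]
  diff <- ca != cb
  # code sums identify mismatch type: A(1)+G(3)=4, C(2)+T(4)=6 are the
  # only mismatching pairs with these sums.
  s <- ca + cb
  ts <- sum(diff & (s == 4L | s == 6L))
  list(n = length(ca), mismatches = sum(diff),
       transitions = ts, transversions = sum(diff) - ts)
}

#' Uncorrected (p) distance
#'
#' Proportion of mismatching sites among comparable sites.
#'
#' @inheritParams comparable_sites
#' @return A number in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  cs <- comparable_sites(a, b)
  if (cs$n == 0L) stop("no comparable sites between sequences")
  cs$mismatches / cs$n
}

# JC69 correction from a raw proportion p.
jc69_from_p <- function(p) {
  if (p >= 0.75)
    stop("saturation: p-distance ", format(p),
         " outside the JC69 domain (p < 0.75)")
  -0.75 * log(1 - 4 * p / 3)
}

# K80 correction from transition/transversion proportions.
k80_from_pq <- function(P, Q) {
  if ((1 - 2 * P - Q) <= 0 || (1 - 2 * Q) <= 0)
    stop("saturation: transition/transversion proportions (P=", format(P),
         ", Q=", format(Q), ") outside the K80 domain")
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

#' Jukes-Cantor (JC69) distance
#'
#' `d = -(3/4) log(1 - 4p/3)` where `p` is the p-distance; assumes equal
#' base frequencies and a single substitution rate.
#'
#' @inheritParams comparable_sites
#' @return Substitutions per site (non-negative).
#' @export
jc69_distance <- function(a, b) {
  jc69_from_p(p_distance(a, b))
}

#' Kimura two-parameter (K80) distance
#'
#' `d = -(1/2) log(1 - 2P - Q) - (1/4) log(1 - 2Q)` where `P` and `Q` are
#' the transition and transversion proportions estimated from the pair
#' itself (no assumed TS/TV ratio enters the formula).
#'
#' @inheritParams comparable_sites
#' @return Substitutions per site (non-negative).
#' @export
k80_distance <- function(a, b) {
  cs <- comparable_sites(a, b)
  if (cs$n == 0L) stop("no comparable sites between sequences")
  k80_from_pq(cs$transitions / cs$n, cs$transversions / cs$n)
}

#' Pairwise genetic distance matrix
#'
#' Computes all unordered pairs of an aligned dataset under one of the
#' three supported models, with pairwise deletion of gap/ambiguous sites.
#'
#' @param ds an aligned `BarcodeDataset` with at least two records.
#' @param model `"simple"` (p-distance), `"jc69"` or `"k80"`.
#' @param mode `"strict"` (default): any pair on which the model is
#'   undefined (saturation, no comparable sites) is an error naming the
#'   pair. `"lenient"`: such entries are stored as `NA` and excluded
#'   downstream.
#' @return A symmetric numeric matrix with record ids as dimnames, zero
#'   diagonal, and attributes `model` and `class = "DistanceMatrix"`.
#' @export
distance_matrix <- function(ds, model = c("simple", "jc69", "k80"),
                            mode = c("strict", "lenient")) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  if (!ds$aligned) stop("distance_matrix requires an aligned dataset")
  n <- n_records(ds)
  if (n < 2L) stop("distance_matrix requires at least two records")
  ids <- ds$records$record_id
  codes <- t(vapply(ds$records$sequence, encode_codes,
                    integer(nchar(ds$records$sequence[1]))))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    ci <- codes[i, ]
    for (j in seq.int(i + 1L, n)) {
      cj <- codes[j, ]
      ok <- !is.na(ci) & !is.na(cj)
      nn <- sum(ok)
      val <- tryCatch({
        if (nn == 0L) stop("no comparable sites")
        mm <- ci[ok] != cj[ok]
        if (model == "simple") {
          sum(mm) / nn
        } else if (model == "jc69") {
          jc69_from_p(sum(mm) / nn)
        } else {
          s <- (ci[ok] + cj[ok])[mm]
          ts <- sum(s == 4L | s == 6L)
          k80_from_pq(ts / nn, (sum(mm) - ts) / nn)
        }
      }, error = function(e) {
        if (mode == "strict")
          stop("distance undefined for pair (", ids[i], ", ", ids[j],
               "): ", conditionMessage(e), call. = FALSE)
        NA_real_
      })
      d[i, j] <- d[j, i] <- val
    }
  }
  structure(d, model = model, class = c("DistanceMatrix", "matrix", "array"))
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  cat(sprintf("DistanceMatrix (%s model), %d records\n",
              attr(x, "model"), nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Write a distance matrix as square TSV
#'
#' @param dm a `DistanceMatrix`.
#' @param path output path.
#' @param phylip_header prepend a PHYLIP-style count line.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path, phylip_header = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (phylip_header) writeLines(as.character(nrow(dm)), con)
  writeLines(paste(c("id", colnames(dm)), collapse = "\t"), con)
  for (i in seq_len(nrow(dm)))
    writeLines(paste(c(rownames(dm)[i],
                       format(dm[i, ], digits = 15, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}
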