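#' Pooled intraspecific distances
#'
#' All unordered conspecific pair distances, pooled over species.
#' Singleton species contribute nothing. `NA` entries (lenient distance
#' matrices) are dropped.
#'
#' @param dm a `DistanceMatrix`.
#' @param ds the matching `BarcodeDataset` (labels aligned by record id).
#' @return Numeric vector of distances.
#' @export
intraspecific_distances <- function(dm, ds) {
  sp <- ds$records$species[match(rownames(dm), ds$records$record_id)]
  if (anyNA(sp)) stop("distance matrix labels not found in dataset")
  same <- outer(sp, sp, "==") & upper.tri(dm)
  vals <- dm[same]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L)
    stop("no species with >= 2 members: intraspecific threshold undefined")
  vals
}

#' Percentile threshold of a distance sample
#'
#' q-th percentile under linear interpolation between order statistics
#' (the convention of `stats::quantile(type = 7)`).
#'
#' @param values non-empty numeric vector.
#' @param q percentile in `(0, 100]`.
#' @return A single number.
#' @export
percentile_threshold <- function(values, q = 95) {
  if (length(values) == 0L) stop("empty distance sample")
  stopifnot(q > 0, q <= 100)
  unname(stats::quantile(values, q / 100, type = 7, names = FALSE))
}

# Shared per-record machinery: distances from the query to everyone else,
# split into conspecific / allospecific.
.query_context <- function(dm, sp, idx) {
  d <- dm[idx, ]
  d <- d[-idx]
  others <- sp[-idx]
  list(d = d, consp = others == sp[idx])
}

.outcome <- function(record_id, criterion, category, best_match_ids,
                     best_distance) {
  list(record_id = record_id, criterion = criterion, category = category,
       best_match_ids = best_match_ids, best_distance = best_distance)
}

#' Best Match identification of one record
#'
#' The query takes the species of its nearest neighbour(s) regardless of
#' similarity. All records tied (within `1e-12`) at the minimal distance
#' count: Correct if every tied best match is conspecific, Incorrect if
#' every one is allospecific, Ambiguous if the tie mixes both.
#'
#' @param dm a `DistanceMatrix`.
#' @param ds the matching `BarcodeDataset`.
#' @param record_id id of the query record.
#' @return An identification outcome list (`record_id`, `criterion`,
#'   `category`, `best_match_ids`, `best_distance`).
#' @export
best_match <- function(dm, ds, record_id) {
  sp <- ds$records$species[match(rownames(dm), ds$records$record_id)]
  idx <- match(record_id, rownames(dm))
  if (is.na(idx)) stop("unknown record id: ", record_id)
  ctx <- .query_context(dm, sp, idx)
  dmin <- min(ctx$d, na.rm = TRUE)
  tied <- which(!is.na(ctx$d) & ctx$d <= dmin + .DIST_EPS)
  hit <- ctx$consp[tied]
  category <- if (all(hit)) "Correct" else if (all(!hit)) "Incorrect"
              else "Ambiguous"
  .outcome(record_id, "BM", category,
           names(ctx$d)[tied], dmin)
}

#' Best Close Match identification of one record
#'
#' Best Match with a distance ceiling: if the nearest neighbour lies
#' beyond `threshold` the query is NoMatch; otherwise the Best Match rule
#' applies.
#'
#' @inheritParams best_match
#' @param threshold distance ceiling (e.g. `0.03`, or a
#'   [percentile_threshold()] of the intraspecific distances).
#' @return An identification outcome list.
#' @export
best_close_match <- function(dm, ds, record_id, threshold = 0.03) {
  out <- best_match(dm, ds, record_id)
  out$criterion <- "BCM"
  if (out$best_distance > threshold + .DIST_EPS) {
    out$category <- "NoMatch"
    out$best_match_ids <- character()
  }
  out
}

#' All Species Barcodes identification of one record
#'
#' The strictest criterion: the query is Correct only when *all* of its
#' conspecifics rank strictly ahead of every allospecific record and all
#' lie within the threshold. An allospecific tying (within `1e-12`) the
#' farthest conspecific makes the query Ambiguous; an allospecific
#' strictly closer than some conspecific makes it Incorrect. If no record
#' at all lies within the threshold the query is NoMatch. A query with no
#' conspecifics in the database (singleton species) can never be Correct.
#'
#' @inheritParams best_close_match
#' @return An identification outcome list.
#' @export
all_species_barcodes <- function(dm, ds, record_id, threshold = 0.03) {
  sp <- ds$records$species[match(rownames(dm), ds$records$record_id)]
  idx <- match(record_id, rownames(dm))
  if (is.na(idx)) stop("unknown record id: ", record_id)
  ctx <- .query_context(dm, sp, idx)
  d <- ctx$d
  dmin <- min(d, na.rm = TRUE)
  if (dmin > threshold + .DIST_EPS)
    return(.outcome(record_id, "ASB", "NoMatch", character(), dmin))
  dc <- d[ctx$consp & !is.na(d)]
  da <- d[!ctx$consp & !is.na(d)]
  if (length(dc) == 0L)
    return(.outcome(record_id, "ASB", "Incorrect",
                    names(d)[which.min(d)], dmin))
  dmax_c <- max(dc)
  dmin_a <- if (length(da)) min(da) else Inf
  category <-
    if (dmin_a < dmax_c - .DIST_EPS) "Incorrect"
    else if (abs(dmin_a - dmax_c) <= .DIST_EPS) "Ambiguous"
    else if (dmax_c <= threshold + .DIST_EPS) "Correct"
    else "Incorrect"  # ordering holds but a conspecific exceeds the threshold
  .outcome(record_id, "ASB", category,
           names(d)[!is.na(d) & ctx$consp], dmax_c)
}

#' Identify every record of a dataset under one criterion
#'
#' Runs [best_match()], [best_close_match()] or [all_species_barcodes()]
#' on every record and rolls the outcomes up to sequence- and
#' species-level percentages.
#'
#' @param dm a `DistanceMatrix`.
#' @param ds the matching `BarcodeDataset`.
#' @param criterion `"BM"`, `"BCM"` or `"ASB"`.
#' @param threshold distance ceiling for BCM/ASB; either a number or the
#'   string `"percentile:95"` (any percentile) to derive it from the
#'   pooled intraspecific distances. Ignored for BM.
#' @param nomatch_vetoes_true if `TRUE`, a NoMatch sequence also vetoes
#'   its species' TRUE status (default `FALSE`: only Incorrect/Ambiguous
#'   veto).
#' @return An `IdentificationReport`: per-record outcomes plus
#'   `pct_correct`, `pct_incorrect`, `pct_ambiguous`, `pct_nomatch`,
#'   `species_correct_pct`, `true_species_pct` and the threshold used.
#' @export
identify_dataset <- function(dm, ds, criterion = c("BM", "BCM", "ASB"),
                             threshold = 0.03,
                             nomatch_vetoes_true = FALSE) {
  criterion <- match.arg(criterion)
  thr <- resolve_threshold(threshold, dm, ds)
  ids <- rownames(dm)
  fun <- switch(criterion,
    BM = function(id) best_match(dm, ds, id),
    BCM = function(id) best_close_match(dm, ds, id, thr),
    ASB = function(id) all_species_barcodes(dm, ds, id, thr))
  outcomes <- lapply(ids, fun)
  cats <- vapply(outcomes, `[[`, character(1), "category")
  n <- length(cats)
  pct <- function(what) 100 * sum(cats == what) / n
  roll <- rollup_species(outcomes, ds,
                         nomatch_vetoes_true = nomatch_vetoes_true)
  structure(
    list(criterion = criterion, outcomes = outcomes, threshold = thr,
         pct_correct = pct("Correct"), pct_incorrect = pct("Incorrect"),
         pct_ambiguous = pct("Ambiguous"), pct_nomatch = pct("NoMatch"),
         species_correct_pct = roll$species_correct_pct,
         true_species_pct = roll$true_species_pct),
    class = "IdentificationReport")
}

#' @export
print.IdentificationReport <- function(x, ...) {
  cat(sprintf(
    paste0("IdentificationReport [%s, threshold %.4g]\n",
           "  sequences: %.2f%% correct, %.2f%% incorrect, ",
           "%.2f%% ambiguous, %.2f%% no match\n",
           "  species:   %.2f%% correct, %.2f%% true species\n"),
    x$criterion, x$threshold, x$pct_correct, x$pct_incorrect,
    x$pct_ambiguous, x$pct_nomatch, x$species_correct_pct,
    x$true_species_pct))
  invisible(x)
}

# Threshold may be numeric or "percentile:<q>".
resolve_threshold <- function(threshold, dm, ds) {
  if (is.numeric(threshold)) return(threshold)
  if (is.character(threshold) && grepl("^percentile:", threshold)) {
    q <- as.numeric(sub("^percentile:", "", threshold))
    return(percentile_threshold(intraspecific_distances(dm, ds), q))
  }
  stop("threshold must be numeric or 'percentile:<q>'")
}

#' Species-level rollup of per-record outcomes
#'
#' A species counts as Correct when at least one of its sequences is
#' Correct; it counts as a TRUE SPECIES when at least one sequence is
#' Correct and none is Incorrect or Ambiguous (NoMatch does not veto by
#' default). The two rules are computed independently.
#'
#' @param outcomes list of per-record outcome lists (one criterion).
#' @param ds the matching `BarcodeDataset`.
#' @param nomatch_vetoes_true stricter reading in which NoMatch also
#'   vetoes TRUE status.
#' @return A list with `species_correct_pct` and `true_species_pct`.
#' @export
rollup_species <- function(outcomes, ds, nomatch_vetoes_true = FALSE) {
  ids <- vapply(outcomes, `[[`, character(1), "record_id")
  cats <- vapply(outcomes, `[[`, character(1), "category")
  sp <- ds$records$species[match(ids, ds$records$record_id)]
  veto <- c("Incorrect", "Ambiguous",
            if (nomatch_vetoes_true) "NoMatch")
  by_sp <- split(cats, sp)
  correct <- vapply(by_sp, function(x) any(x == "Correct"), logical(1))
  true_sp <- vapply(by_sp, function(x)
    any(x == "Correct") && !any(x %in% veto), logical(1))
  n_sp <- length(unique(ds$records$species))
  list(species_correct_pct = 100 * sum(correct) / n_sp,
       true_species_pct = 100 * sum(true_sp) / n_sp)
}

#' Per-record outcomes as a data frame
#'
#' @param report an `IdentificationReport`.
#' @return A data.frame with one row per record.
#' @export
outcomes_table <- function(report) {
  data.frame(
    record_id = vapply(report$outcomes, `[[`, character(1), "record_id"),
    criterion = vapply(report$outcomes, `[[`, character(1), "criterion"),
    category = vapply(report$outcomes, `[[`, character(1), "category"),
    best_distance = vapply(report$outcomes, `[[`, numeric(1),
                           "best_distance"),
    best_match_ids = vapply(report$outcomes, function(o)
      paste(o$best_match_ids, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}
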