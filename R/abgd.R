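#' Geometric series of prior maximal intraspecific divergences
#'
#' @param p_min,p_max series bounds, `0 < p_min < p_max`.
#' @param steps series length (>= 2).
#' @return Numeric vector of `steps` priors, geometric from `p_min` to
#'   `p_max` inclusive.
#' @export
prior_series <- function(p_min = 0.001, p_max = 0.1, steps = 10) {
  if (!(p_min > 0 && p_min < p_max)) stop("require 0 < p_min < p_max")
  if (steps < 2) stop("steps must be >= 2")
  exp(seq(log(p_min), log(p_max), length.out = steps))
}

#' Detect the first significant barcode gap beyond a prior divergence
#'
#' Scans successive gaps `g_i = d_(i+1) - d_(i)` of the sorted distances.
#' A gap is a candidate once it reaches beyond the prior
#' (`d_(i+1) >= prior_p`, so a gap straddling the prior counts), and is
#' significant when it exceeds `X` times the local mean gap `w(i)`,
#' computed over a sliding window of the `ceiling(N/10)` ranked gaps on
#' either side (capped at the data). Returns the midpoint of the first
#' significant gap, or `NULL` when none exists (e.g. uniformly spaced
#' distances, or all distances below the prior).
#'
#' @param sorted_distances ascending numeric vector (length >= 2).
#' @param prior_p prior maximal intraspecific divergence.
#' @param X relative gap width a candidate must exceed.
#' @return Midpoint of the detected gap, or `NULL`.
#' @export
detect_gap <- function(sorted_distances, prior_p, X = 1.5) {
  d <- sorted_distances
  N <- length(d)
  if (N < 2L) return(NULL)
  if (is.unsorted(d)) stop("distances must be sorted ascending")
  g <- diff(d)
  h <- ceiling(N / 10)
  for (i in seq_along(g)) {
    if (d[i + 1L] < prior_p) next
    lo <- max(1L, i - h)
    hi <- min(length(g), i + h)
    w <- mean(g[lo:hi])
    if (g[i] > X * w) return((d[i] + d[i + 1L]) / 2)
  }
  NULL
}

# Single-linkage connected components of the graph joining pairs with
# distance <= threshold. `values` is a plain symmetric matrix; returns a
# list of integer index vectors.
.slink_components <- function(values, threshold) {
  n <- nrow(values)
  adj <- !is.na(values) & values <= threshold
  seen <- logical(n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    members <- integer()
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      members <- c(members, v)
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

#' Partition records at a fixed distance threshold
#'
#' Single-linkage: groups are the connected components of the graph that
#' joins every pair at distance `<= threshold`.
#'
#' @param dm a `DistanceMatrix`.
#' @param threshold non-negative distance threshold.
#' @return A `Partition`: list with `prior_p` (`NA` here), `groups` (list
#'   of record-id character vectors) and `gap_threshold`.
#' @export
partition_at_threshold <- function(dm, threshold) {
  stopifnot(threshold >= 0)
  comps <- .slink_components(unclass(dm), threshold)
  new_partition(lapply(comps, function(ix) rownames(dm)[ix]),
                prior_p = NA_real_, gap_threshold = threshold)
}

new_partition <- function(groups, prior_p, gap_threshold) {
  structure(list(prior_p = prior_p, groups = groups,
                 gap_threshold = gap_threshold),
            class = "Partition")
}

#' @export
print.Partition <- function(x, ...) {
  cat(sprintf("Partition: %d groups (prior %.4g, gap threshold %s)\n",
              length(x$groups), x$prior_p,
              if (is.na(x$gap_threshold %||% NA)) "none"
              else format(x$gap_threshold, digits = 4)))
  invisible(x)
}

#' Recursive barcode-gap partitioning at one prior
#'
#' Applies [detect_gap()] + single-linkage partitioning to the whole
#' dataset, then re-applies the same procedure within each resulting
#' group (distances restricted to the group) until no group splits
#' further. Recursion stops on groups of fewer than 3 records. When no
#' significant gap exists anywhere, a single group is returned.
#'
#' @param dm a `DistanceMatrix`.
#' @param prior_p prior maximal intraspecific divergence.
#' @param X relative gap width.
#' @return A `Partition` whose `gap_threshold` is the top-level detected
#'   gap (or `NA` if none).
#' @export
recursive_partition <- function(dm, prior_p, X = 1.5) {
  values <- unclass(dm)
  ids <- rownames(values)
  top_thr <- NA_real_
  split_group <- function(ix, top_level = FALSE) {
    if (length(ix) < 3L) return(list(ix))
    sub <- values[ix, ix, drop = FALSE]
    d <- sort(sub[upper.tri(sub)])
    d <- d[!is.na(d)]
    thr <- detect_gap(d, prior_p, X)
    if (is.null(thr)) return(list(ix))
    if (top_level) top_thr <<- thr
    comps <- .slink_components(sub, thr)
    if (length(comps) == 1L) return(list(ix))
    unlist(lapply(comps, function(c_ix) split_group(ix[c_ix])),
           recursive = FALSE)
  }
  groups <- split_group(seq_along(ids), top_level = TRUE)
  new_partition(lapply(groups, function(ix) ids[ix]),
                prior_p = prior_p, gap_threshold = top_thr)
}

#' Partition scan across a prior-divergence series
#'
#' @param dm a `DistanceMatrix`.
#' @param p_min,p_max,steps arguments of [prior_series()].
#' @param X relative gap width.
#' @return A list of `Partition`s, one per prior (ascending).
#' @export
abgd_scan <- function(dm, p_min = 0.001, p_max = 0.1, steps = 10,
                      X = 1.5) {
  lapply(prior_series(p_min, p_max, steps),
         function(p) recursive_partition(dm, p, X))
}

#' Select the initial partition from a prior scan
#'
#' Returns the partition whose group count equals the modal group count
#' across the series; ties (in modal frequency or within the modal count)
#' are broken toward the smaller prior.
#'
#' @param partitions non-empty list of `Partition`s ordered by ascending
#'   prior.
#' @return A single `Partition`.
#' @export
select_initial_partition <- function(partitions) {
  if (length(partitions) == 0L) stop("empty partition list")
  counts <- vapply(partitions, function(p) length(p$groups), integer(1))
  tab <- table(counts)
  modal <- as.integer(names(tab)[tab == max(tab)])
  # among equally frequent counts, take the one first reached in the scan
  first_idx <- vapply(modal, function(m) which(counts == m)[1L], integer(1))
  partitions[[min(first_idx)]]
}

#' Categorise the groups of a partition against species labels
#'
#' Per group: `SINGLETON` if it holds exactly one record; `TRUE` if all
#' records belong to one species and that species occurs in no other
#' group; `AMBIGUOUS` if the group is pure but its species is split
#' across groups; `INCORRECT` if several species co-occur.
#'
#' @param part a `Partition`.
#' @param ds the matching `BarcodeDataset`.
#' @return A list with `tags` (character per group), `pct_sequences`
#'   (named percentages of sequences in each tag) and `true_species_pct`
#'   (percentage of species that form a TRUE group).
#' @export
categorize_groups <- function(part, ds) {
  sp_of <- function(idv)
    ds$records$species[match(idv, ds$records$record_id)]
  group_sp <- lapply(part$groups, sp_of)
  n_groups_with <- function(species)
    sum(vapply(group_sp, function(g) species %in% g, logical(1)))
  tags <- vapply(seq_along(part$groups), function(i) {
    g <- group_sp[[i]]
    if (length(g) == 1L) return("SINGLETON")
    u <- unique(g)
    if (length(u) > 1L) return("INCORRECT")
    if (n_groups_with(u) > 1L) "AMBIGUOUS" else "TRUE"
  }, character(1))
  sizes <- lengths(part$groups)
  n_seq <- sum(sizes)
  pct_seq <- vapply(c(TRUE. = "TRUE", INCORRECT = "INCORRECT",
                      AMBIGUOUS = "AMBIGUOUS", SINGLETON = "SINGLETON"),
                    function(t) 100 * sum(sizes[tags == t]) / n_seq,
                    numeric(1))
  names(pct_seq) <- c("TRUE", "INCORRECT", "AMBIGUOUS", "SINGLETON")
  n_species <- length(unique(ds$records$species))
  list(tags = tags,
       pct_sequences = pct_seq,
       true_species_pct = 100 * sum(tags == "TRUE") / n_species)
}

#' Summary table of a prior scan
#'
#' One row per prior: number of groups plus the sequence/species
#' percentages of [categorize_groups()].
#'
#' @param partitions list of `Partition`s from [abgd_scan()].
#' @param ds the matching `BarcodeDataset`.
#' @return A data.frame.
#' @export
abgd_summary <- function(partitions, ds) {
  rows <- lapply(partitions, function(p) {
    cat_ <- categorize_groups(p, ds)
    data.frame(prior_p = p$prior_p, n_groups = length(p$groups),
               pct_true = cat_$pct_sequences[["TRUE"]],
               pct_incorrect = cat_$pct_sequences[["INCORRECT"]],
               pct_ambiguous = cat_$pct_sequences[["AMBIGUOUS"]],
               pct_singleton = cat_$pct_sequences[["SINGLETON"]],
               true_species_pct = cat_$true_species_pct)
  })
  do.call(rbind, rows)
}

#' Histogram of pairwise distances
#'
#' Diagnostic mirror of the web tool's distance histogram; the bin count
#' plays no role in gap detection.
#'
#' @param dm a `DistanceMatrix`.
#' @param n_bins number of equal-width bins.
#' @return A data.frame with bin midpoints and counts.
#' @export
distance_histogram <- function(dm, n_bins = 20) {
  d <- dm[upper.tri(dm)]
  d <- d[!is.na(d)]
  breaks <- seq(min(d), max(d), length.out = n_bins + 1L)
  if (min(d) == max(d)) breaks <- c(min(d) - 1e-9, max(d) + 1e-9)
  h <- hist(d, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}
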