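#' Mutate a nucleotide sequence at a per-site substitution probability
#'
#' Each site is substituted independently with probability `rate`. Under
#' the default uniform (JC-like) scheme the replacement is uniform over
#' the three alternative bases; with a transition/transversion ratio
#' `tstv = R`, a substitution is the transition with probability
#' `R / (R + 1)` and either transversion with probability
#' `1 / (2 (R + 1))`. Non-ACGT positions are left untouched.
#'
#' @param sequence nucleotide string.
#' @param rate per-site substitution probability in `[0, 0.75]`.
#' @param tstv transition/transversion ratio, or `NULL` for uniform.
#' @param seed optional seed (omit to use the current RNG stream).
#' @return The mutated sequence string.
#' @export
mutate_sequence <- function(sequence, rate, tstv = NULL, seed = NULL) {
  if (rate < 0 || rate > 0.75)
    stop("rate must lie in [0, 0.75]")
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  codes <- match(chars, .BASES)
  hit <- which(!is.na(codes) & stats::runif(length(chars)) < rate)
  if (length(hit)) {
    chars[hit] <- vapply(codes[hit], .substitute_base, character(1),
                         tstv = tstv)
  }
  paste(chars, collapse = "")
}

# transition partner per base code (A<->G, C<->T)
.TS_PARTNER <- c(3L, 4L, 1L, 2L)

.substitute_base <- function(code, tstv) {
  if (is.null(tstv)) {
    return(.BASES[sample(setdiff(1:4, code), 1L)])
  }
  p_ts <- tstv / (tstv + 1)
  if (stats::runif(1) < p_ts) .BASES[.TS_PARTNER[code]]
  else .BASES[sample(setdiff(1:4, c(code, .TS_PARTNER[code])), 1L)]
}

# Per-branch substitution rate r such that two sequences independently
# mutated at r from a common source show an expected pairwise p-distance
# of D (uniform substitution): P(differ) = 2r(1-r) + (2/3)r^2 = D.
.branch_rate <- function(D) {
  if (D == 0) return(0)
  0.75 * (1 - sqrt(1 - 4 * D / 3))
}

#' Generate a synthetic multi-species barcode dataset
#'
#' Emulates a curated barcode reference library with a controllable
#' barcode gap. One random ancestor per species is mutated from a common
#' root, and members are mutated from their ancestor, with the per-branch
#' rates calibrated so that the *expected pairwise p-distance* between
#' conspecifics is `intra_divergence` and between species ancestors is
#' `inter_divergence`. A fraction of species are reduced to singletons;
#' indels become gap columns (`-`, aligned output, no realignment) and
#' missing data become `N`.
#'
#' @param n_species number of species.
#' @param members_per_species sequences per (non-singleton) species;
#'   either a single integer or an integer vector sampled from.
#' @param seq_length alignment length in bp.
#' @param intra_divergence expected pairwise p-distance within species
#'   (`0 <= intra < inter`).
#' @param inter_divergence expected pairwise p-distance between species
#'   ancestors (`<= 0.75`).
#' @param singleton_fraction fraction of species reduced to one record.
#' @param indel_rate per-site probability of a gap in each record.
#' @param missing_rate per-site probability of an `N` in each record.
#' @param tstv transition/transversion ratio for substitutions (`NULL`
#'   for uniform).
#' @param seed integer seed; the dataset is byte-identical under a fixed
#'   seed.
#' @param marker marker tag for the dataset.
#' @return A list with `dataset` (an aligned `BarcodeDataset`, species
#'   labels `Species_001`, ...) and `truth` (a data.frame mapping
#'   `record_id` to the true species).
#' @export
generate_dataset <- function(n_species = 20, members_per_species = 4,
                             seq_length = 600,
                             intra_divergence = 0.005,
                             inter_divergence = 0.08,
                             singleton_fraction = 0,
                             indel_rate = 0, missing_rate = 0,
                             tstv = NULL, seed = 1, marker = "synthetic") {
  stopifnot(n_species >= 1, seq_length >= 1,
            all(members_per_species >= 1),
            singleton_fraction >= 0, singleton_fraction <= 1,
            indel_rate >= 0, indel_rate < 1,
            missing_rate >= 0, missing_rate < 1)
  if (!(intra_divergence >= 0 && intra_divergence < inter_divergence &&
        inter_divergence <= 0.75))
    stop("require 0 <= intra_divergence < inter_divergence <= 0.75")
  set.seed(seed)
  r_intra <- .branch_rate(intra_divergence)
  r_inter <- .branch_rate(inter_divergence)
  root <- paste(sample(.BASES, seq_length, replace = TRUE),
                collapse = "")
  n_singletons <- round(singleton_fraction * n_species)
  singletons <- if (n_singletons > 0)
    sample.int(n_species, n_singletons) else integer(0)
  ids <- character(0); species <- character(0); seqs <- character(0)
  for (s in seq_len(n_species)) {
    anc <- mutate_sequence(root, r_inter, tstv = tstv)
    m <- if (s %in% singletons) 1L
         else if (length(members_per_species) > 1L)
           sample(members_per_species, 1L)
         else as.integer(members_per_species)
    sp_name <- sprintf("Species_%03d", s)
    for (j in seq_len(m)) {
      seq_j <- mutate_sequence(anc, r_intra, tstv = tstv)
      if (indel_rate > 0 || missing_rate > 0) {
        chars <- strsplit(seq_j, "", fixed = TRUE)[[1]]
        u <- stats::runif(seq_length)
        chars[u < indel_rate] <- "-"
        miss <- u >= indel_rate & u < indel_rate + missing_rate
        chars[miss] <- "N"
        seq_j <- paste(chars, collapse = "")
      }
      ids <- c(ids, sprintf("SYN%03d_%02d", s, j))
      species <- c(species, sp_name)
      seqs <- c(seqs, seq_j)
    }
  }
  ds <- barcode_dataset(ids, species, seqs, marker = marker,
                        aligned = TRUE)
  list(dataset = ds,
       truth = data.frame(record_id = ids, species = species,
                          stringsAsFactors = FALSE))
}
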