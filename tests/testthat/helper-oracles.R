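# Independent brute-force oracles and small dataset builders. These stay
# deliberately naive (explicit enumeration) so they can vouch for the
# optimised implementations.

BASES4 <- c("A", "C", "G", "T")

random_seq <- function(L, bases = BASES4) {
  paste(sample(bases, L, replace = TRUE), collapse = "")
}

# every word of {A,C,G,T}^k, own enumeration order
oracle_words <- function(k) {
  w <- ""
  for (i in seq_len(k)) w <- as.vector(outer(w, BASES4, paste0))
  w
}

# naive sliding-window spectrum counts, named by word
oracle_spectrum <- function(s, k) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  counts <- setNames(numeric(4^k), oracle_words(k))
  L <- length(chars)
  if (L >= k) for (i in 1:(L - k + 1)) {
    w <- paste(chars[i:(i + k - 1)], collapse = "")
    if (w %in% names(counts)) counts[w] <- counts[w] + 1
  }
  counts
}

# all position k-tuples with span <= k-1+g
oracle_gappy <- function(s, k, g) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  counts <- setNames(numeric(4^k), oracle_words(k))
  L <- length(chars)
  if (L >= k) for (tuple in utils::combn(L, k, simplify = FALSE)) {
    if (tuple[k] - tuple[1] > k - 1 + g) next
    w <- paste(chars[tuple], collapse = "")
    if (w %in% names(counts)) counts[w] <- counts[w] + 1
  }
  counts
}

# all contiguous instances within Hamming distance <= m of each word
oracle_mismatch <- function(s, k, m) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  words <- oracle_words(k)
  counts <- setNames(numeric(4^k), words)
  L <- length(chars)
  if (L < k) return(counts)
  split_words <- strsplit(words, "", fixed = TRUE)
  for (i in 1:(L - k + 1)) {
    inst <- chars[i:(i + k - 1)]
    if (!all(inst %in% BASES4)) next
    for (j in seq_along(words)) {
      if (sum(inst != split_words[[j]]) <= m)
        counts[j] <- counts[j] + 1
    }
  }
  counts
}

# feature row (raw counts) of a single sequence, by scheme; the
# shorter-than-k warning is by design and irrelevant to the oracles
feature_row <- function(s, fun, ...) {
  ds <- barcode_dataset("q", "Q_sp", s)
  suppressWarnings(fun(ds, ..., raw = TRUE)$values[1, ])
}

# tiny aligned dataset builder
toy_dataset <- function(sequences, species,
                        ids = sprintf("R%02d", seq_along(sequences)),
                        aligned = TRUE) {
  barcode_dataset(ids, species, sequences, marker = "toy",
                  aligned = aligned)
}

# planted-gap dataset used across acceptance tests (the stated world)
planted_gap_dataset <- function(seed = 1, singleton_fraction = 0) {
  generate_dataset(n_species = 20, members_per_species = 4,
                   seq_length = 600, intra_divergence = 0.005,
                   inter_divergence = 0.08,
                   singleton_fraction = singleton_fraction, seed = seed)
}
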