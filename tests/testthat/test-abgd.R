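test_that("prior_series is geometric and validates bounds", {
  expect_equal(prior_series(0.001, 0.1, 3), c(0.001, 0.01, 0.1))
  expect_equal(prior_series(0.02, 0.5, 2), c(0.02, 0.5))
  expect_equal(length(prior_series()), 10)
  expect_error(prior_series(0.1, 0.1), "p_min < p_max")
  expect_error(prior_series(0.1, 0.01), "p_min < p_max")
})

test_that("detect_gap finds the first significant gap beyond the prior", {
  # dense low block, dense high block, 0.05 jump in between
  d <- sort(c(seq(0.001, 0.01, length.out = 30),
              seq(0.06, 0.09, length.out = 30)))
  thr <- detect_gap(d, prior_p = 0.02, X = 1.5)
  expect_true(!is.null(thr) && thr > 0.01 && thr < 0.06)

  # uniformly spaced distances: every gap equals the local mean
  expect_null(detect_gap(seq(0.01, 0.2, by = 0.01), 0.02, 1.5))

  # all distances below the prior
  expect_null(detect_gap(seq(0.001, 0.01, length.out = 40), 0.5, 1.5))
})

test_that("partition_at_threshold gives single-linkage components", {
  g <- generate_dataset(n_species = 3, members_per_species = 4,
                        seq_length = 200, intra_divergence = 0.01,
                        inter_divergence = 0.2, seed = 2)
  dm <- distance_matrix(g$dataset, "simple")

  d_pos <- dm[upper.tri(dm)]
  if (min(d_pos) > 0) {
    below <- partition_at_threshold(dm, min(d_pos) / 2)
    expect_equal(length(below$groups), nrow(dm))
  }
  # all-distinct toy set: threshold below every distance isolates records
  toy <- toy_dataset(c("AAAA", "AATT", "TTTT", "GGGG"),
                     c("a", "a", "b", "c"))
  dmt <- distance_matrix(toy, "simple")
  expect_equal(length(partition_at_threshold(dmt, 0.1)$groups), 4L)
  above <- partition_at_threshold(dm, 1)
  expect_equal(length(above$groups), 1L)

  mid <- partition_at_threshold(dm, 0.05)
  truth <- split(g$truth$record_id, g$truth$species)
  expect_equal(length(mid$groups), 3L)
  expect_setequal(lapply(mid$groups, sort), lapply(truth, sort))

  # brute-force transitive closure oracle
  adj <- unclass(dm) <= 0.05
  reach <- adj
  for (k in seq_len(nrow(adj)))
    reach <- reach | (reach %*% reach > 0)
  oracle_groups <- unique(apply(reach, 1, function(r)
    paste(sort(rownames(dm)[r]), collapse = ",")))
  expect_setequal(vapply(mid$groups, function(g_)
    paste(sort(g_), collapse = ","), character(1)), oracle_groups)

  # coarsening: group count non-increasing in threshold
  counts <- vapply(seq(0, 0.3, by = 0.02), function(t)
    length(partition_at_threshold(dm, t)$groups), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("recursive_partition matches the iterated non-recursive oracle", {
  iterate_oracle <- function(dm, prior, X) {
    values <- unclass(dm)
    groups <- list(rownames(values))
    repeat {
      nxt <- list()
      changed <- FALSE
      for (ids in groups) {
        if (length(ids) < 3) { nxt <- c(nxt, list(ids)); next }
        sub <- values[ids, ids]
        thr <- detect_gap(sort(sub[upper.tri(sub)]), prior, X)
        comps <- if (is.null(thr)) list(ids) else {
          p <- partition_at_threshold(
            structure(sub, class = c("DistanceMatrix", "matrix", "array")),
            thr)
          p$groups
        }
        if (length(comps) > 1) changed <- TRUE
        nxt <- c(nxt, comps)
      }
      groups <- nxt
      if (!changed) return(groups)
    }
  }
  for (seed in c(4, 8, 15)) {
    g <- generate_dataset(n_species = 5, members_per_species = 4,
                          seq_length = 150, intra_divergence = 0.01,
                          inter_divergence = 0.15, seed = seed)
    dm <- distance_matrix(g$dataset, "simple")
    for (prior in c(0.005, 0.02)) {
      mine <- recursive_partition(dm, prior, 1.5)
      oracle <- iterate_oracle(dm, prior, 1.5)
      expect_setequal(lapply(mine$groups, sort), lapply(oracle, sort))
      # true set partition at every level
      expect_setequal(unlist(mine$groups), rownames(dm))
      expect_equal(anyDuplicated(unlist(mine$groups)), 0L)
    }
  }
})

test_that("recursive_partition handles degenerate and hierarchical input", {
  # no significant gap anywhere -> one group
  ds <- toy_dataset(c("AAAA", "AAAT", "AATT", "ATTT"), rep("s", 4))
  dm <- distance_matrix(ds, "simple")
  expect_equal(length(recursive_partition(dm, 0.01, 1.5)$groups), 1L)

  # two records: below the recursion minimum, one group
  two <- toy_dataset(c("AAAA", "TTTT"), c("a", "b"))
  dm2 <- distance_matrix(two, "simple")
  expect_equal(length(recursive_partition(dm2, 0.01, 1.5)$groups), 1L)

  # planted two-level hierarchy: subclusters at p ~ .03, outgroup ~ .5
  base <- strrep("ACGT", 25)
  far <- paste0(strrep("T", 50), substr(base, 51, 100))
  mk <- function(s, n) replicate(n, s)
  sub2 <- paste0(strrep("G", 3), substr(base, 4, 100))
  seqs <- c(mk(base, 3), mk(sub2, 3), mk(far, 3))
  ds3 <- toy_dataset(seqs, rep(c("a1", "a2", "b"), each = 3))
  dm3 <- distance_matrix(ds3, "simple")
  part <- recursive_partition(dm3, 0.005, 1.5)
  expect_equal(length(part$groups), 3L)
})

test_that("select_initial_partition picks the modal group count", {
  fake <- function(n_groups, prior) {
    partition_at_threshold  # silence lints
    structure(list(prior_p = prior,
                   groups = as.list(seq_len(n_groups)),
                   gap_threshold = NA_real_), class = "Partition")
  }
  parts <- Map(fake, c(9, 5, 5, 5, 2), c(0.001, 0.003, 0.01, 0.03, 0.1))
  sel <- select_initial_partition(parts)
  expect_equal(length(sel$groups), 5L)
  expect_equal(sel$prior_p, 0.003)  # first partition with the modal count

  all_same <- Map(fake, c(4, 4, 4), c(0.01, 0.02, 0.04))
  expect_equal(select_initial_partition(all_same)$prior_p, 0.01)

  single <- list(fake(7, 0.05))
  expect_equal(length(select_initial_partition(single)$groups), 7L)
  expect_error(select_initial_partition(list()), "empty")
})

test_that("categorize_groups applies the TRUE/AMBIGUOUS/INCORRECT/SINGLETON rules", {
  ds <- toy_dataset(rep("ACGT", 6), c("A", "A", "B", "B", "C", "A"),
                    ids = paste0("r", 1:6))
  part <- structure(list(
    prior_p = 0.01,
    groups = list(c("r1", "r2"),        # pure A but A also in group 4
                  c("r3", "r4"),        # all of B -> TRUE
                  "r5",                 # singleton
                  c("r6")),             # the remaining A, singleton
    gap_threshold = NA_real_), class = "Partition")
  out <- categorize_groups(part, ds)
  expect_equal(out$tags, c("AMBIGUOUS", "TRUE", "SINGLETON", "SINGLETON"))
  expect_equal(out$true_species_pct, 100 / 3)
  expect_equal(sum(out$pct_sequences), 100)

  # multiple species in one group -> INCORRECT
  part2 <- structure(list(prior_p = 0.01,
                          groups = list(c("r1", "r3"),
                                        c("r2", "r4", "r5", "r6")),
                          gap_threshold = NA_real_), class = "Partition")
  expect_equal(categorize_groups(part2, ds)$tags,
               c("INCORRECT", "INCORRECT"))
})
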