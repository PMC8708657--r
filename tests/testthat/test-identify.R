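# A reusable 4-record, 2-species toy set with hand-computed p-distances:
#   q1 AAAAAAAA, q2 AAAAAAAT (d = .125), r1 TTTTAAAA, r2 TTTTAAAT
toy_two_species <- function() {
  toy_dataset(c("AAAAAAAA", "AAAAAAAT", "TTTTAAAA", "TTTTAAAT"),
              c("spA", "spA", "spB", "spB"),
              ids = c("q1", "q2", "r1", "r2"))
}

test_that("intraspecific_distances pools conspecific pairs only", {
  ds <- toy_two_species()
  dm <- distance_matrix(ds, "simple")
  expect_equal(sort(intraspecific_distances(dm, ds)),
               c(0.125, 0.125))

  # brute-force enumeration oracle on a 3-species set
  set.seed(3)
  base <- random_seq(60)
  seqs <- vapply(1:7, function(i) mutate_sequence(base, 0.1),
                 character(1))
  sp <- c("a", "a", "a", "b", "b", "c", "c")
  ds2 <- toy_dataset(seqs, sp)
  dm2 <- distance_matrix(ds2, "simple")
  brute <- c()
  for (i in 1:6) for (j in (i + 1):7)
    if (sp[i] == sp[j]) brute <- c(brute, dm2[i, j])
  expect_equal(sort(intraspecific_distances(dm2, ds2)), sort(brute))

  singles <- toy_dataset(c("AAAA", "TTTT"), c("x", "y"))
  dms <- distance_matrix(singles, "simple")
  expect_error(intraspecific_distances(dms, singles), "undefined")
})

test_that("percentile_threshold interpolates between order statistics", {
  expect_equal(percentile_threshold(c(0, 0, 0, 0), 95), 0)
  expect_equal(percentile_threshold(1:100, 95), 95.05)
  expect_equal(percentile_threshold(7, 37), 7)
  expect_error(percentile_threshold(numeric(0)), "empty")
})

test_that("best_match categorises by the tied nearest neighbours", {
  ds <- toy_two_species()
  dm <- distance_matrix(ds, "simple")
  expect_equal(best_match(dm, ds, "q1")$category, "Correct")
  expect_equal(best_match(dm, ds, "q1")$best_match_ids, "q2")

  # singleton species query is forced Incorrect
  ds2 <- toy_dataset(c("AAAAAAAA", "TTTTAAAA", "TTTTAAAT"),
                     c("solo", "spB", "spB"),
                     ids = c("s1", "r1", "r2"))
  dm2 <- distance_matrix(ds2, "simple")
  expect_equal(best_match(dm2, ds2, "s1")$category, "Incorrect")

  # exact equidistance to one conspecific and one allospecific
  ds3 <- toy_dataset(c("AAAA", "AAAT", "AAAG"),
                     c("spA", "spA", "spB"),
                     ids = c("q", "cons", "allo"))
  dm3 <- distance_matrix(ds3, "simple")
  out <- best_match(dm3, ds3, "q")
  expect_equal(out$category, "Ambiguous")
  expect_setequal(out$best_match_ids, c("cons", "allo"))
})

test_that("best_close_match demotes distant queries to NoMatch", {
  ds <- toy_two_species()
  dm <- distance_matrix(ds, "simple")
  expect_equal(best_close_match(dm, ds, "q1", 0.3)$category, "Correct")
  # nearest neighbour at 0.125 > threshold 0.1
  expect_equal(best_close_match(dm, ds, "q1", 0.1)$category, "NoMatch")

  # at threshold 0, NoMatch count equals records without a zero-distance
  # neighbour (brute force over random datasets)
  for (seed in 1:5) {
    g <- generate_dataset(n_species = 5, members_per_species = 3,
                          seq_length = 80, intra_divergence = 0.01,
                          inter_divergence = 0.2, seed = seed)
    dm_g <- distance_matrix(g$dataset, "simple")
    rep0 <- identify_dataset(dm_g, g$dataset, "BCM", threshold = 0)
    cats <- outcomes_table(rep0)$category
    no_zero <- sum(vapply(seq_len(nrow(dm_g)), function(i)
      min(dm_g[i, -i]) > 0, logical(1)))
    expect_equal(sum(cats == "NoMatch"), no_zero)
  }
})

test_that("all_species_barcodes requires all conspecifics to outrank allospecifics", {
  # 3 conspecifics at {0, .01}, nearest allospecific .08, threshold .03
  base <- strrep("A", 100)
  seqs <- c(base, base, mutate_sequence(base, 0, seed = 1),
            paste0(strrep("T", 8), strrep("A", 92)))
  seqs[3] <- paste0("G", substr(base, 2, 100))  # one mismatch: d = .01
  ds <- toy_dataset(seqs, c("spA", "spA", "spA", "spB"),
                    ids = c("q", "c1", "c2", "a1"))
  dm <- distance_matrix(ds, "simple")
  expect_equal(all_species_barcodes(dm, ds, "q", 0.03)$category,
               "Correct")

  # an allospecific strictly closer than a conspecific
  ds2 <- toy_dataset(c(strrep("A", 100),
                       paste0("GG", strrep("A", 98)),     # consp at .02
                       paste0("T", strrep("A", 99))),     # allo at .01
                     c("spA", "spA", "spB"),
                     ids = c("q", "c1", "a1"))
  dm2 <- distance_matrix(ds2, "simple")
  expect_equal(all_species_barcodes(dm2, ds2, "q", 0.05)$category,
               "Incorrect")

  # singleton species can never be Correct: Incorrect or NoMatch
  ds3 <- toy_dataset(c(strrep("A", 100), paste0("T", strrep("A", 99))),
                     c("solo", "spB"), ids = c("s", "b"))
  dm3 <- distance_matrix(ds3, "simple")
  expect_equal(all_species_barcodes(dm3, ds3, "s", 0.05)$category,
               "Incorrect")
  expect_equal(all_species_barcodes(dm3, ds3, "s", 0.001)$category,
               "NoMatch")

  # allospecific tying the farthest conspecific -> Ambiguous
  ds4 <- toy_dataset(c(strrep("A", 100),
                       paste0("G", strrep("A", 99)),
                       paste0("T", strrep("A", 99))),
                     c("spA", "spA", "spB"), ids = c("q", "c1", "a1"))
  dm4 <- distance_matrix(ds4, "simple")
  expect_equal(all_species_barcodes(dm4, ds4, "q", 0.05)$category,
               "Ambiguous")
})

test_that("rollup_species applies the TRUE SPECIES veto rules", {
  mk <- function(cats, sp) {
    outcomes <- lapply(seq_along(cats), function(i)
      list(record_id = paste0("r", i), criterion = "BM",
           category = cats[i], best_match_ids = "x", best_distance = 0))
    ds <- toy_dataset(rep("ACGT", length(cats)), sp,
                      ids = paste0("r", seq_along(cats)))
    rollup_species(outcomes, ds)
  }
  both <- mk(c("Correct", "Correct"), c("A", "A"))
  expect_equal(both$species_correct_pct, 100)
  expect_equal(both$true_species_pct, 100)

  amb <- mk(c("Correct", "Ambiguous"), c("A", "A"))
  expect_equal(amb$species_correct_pct, 100)
  expect_equal(amb$true_species_pct, 0)

  nm <- mk(c("Correct", "NoMatch"), c("A", "A"))
  expect_equal(nm$true_species_pct, 100)  # NoMatch does not veto
})

test_that("identify_dataset percentages foot to 100 and support percentile thresholds", {
  ds <- load_fixture("toy_bm")
  dm <- distance_matrix(ds, "simple")
  for (cr in c("BM", "BCM", "ASB")) {
    r <- identify_dataset(dm, ds, cr, threshold = 0.6)
    expect_equal(r$pct_correct + r$pct_incorrect + r$pct_ambiguous +
                   r$pct_nomatch, 100)
  }
  r95 <- identify_dataset(dm, ds, "BCM", threshold = "percentile:95")
  expect_equal(r95$threshold,
               percentile_threshold(intraspecific_distances(dm, ds), 95))
})

test_that("outcomes are invariant to record order", {
  g <- generate_dataset(n_species = 4, members_per_species = 3,
                        seq_length = 100, seed = 9)
  ds <- g$dataset
  dm <- distance_matrix(ds, "simple")
  r <- identify_dataset(dm, ds, "BCM", 0.03)
  perm <- sample(n_records(ds))
  ds2 <- toy_dataset(ds$records$sequence[perm], ds$records$species[perm],
                     ids = ds$records$record_id[perm])
  dm2 <- distance_matrix(ds2, "simple")
  r2 <- identify_dataset(dm2, ds2, "BCM", 0.03)
  t1 <- outcomes_table(r); t2 <- outcomes_table(r2)
  expect_equal(t2$category[match(t1$record_id, t2$record_id)],
               t1$category)
})
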