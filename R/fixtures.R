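# Shipped toy fixtures: tiny hand-verifiable FASTA datasets whose
# expected outputs were enumerated by hand (see the JSON payloads) and
# are recomputed through the public API on demand.

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "barcodekit")
  if (!nzchar(p)) stop("fixture not found: ", name)
  p
}

#' Load a shipped toy fixture dataset
#'
#' @param name `"toy_bm"` (5 records, 3 species, Best Match example) or
#'   `"toy_abgd"` (12 records, 3 planted clusters).
#' @return A `BarcodeDataset`.
#' @export
load_fixture <- function(name = c("toy_bm", "toy_abgd")) {
  name <- match.arg(name)
  read_barcode_fasta(fixture_path(paste0(name, ".fasta")),
                     marker = name, aligned = TRUE)
}

.verify_toy_bm <- function() {
  ds <- load_fixture("toy_bm")
  exp <- jsonlite::read_json(fixture_path("toy_bm_expected.json"),
                             simplifyVector = TRUE)
  dm <- distance_matrix(ds, "simple")
  rep <- identify_dataset(dm, ds, "BM")
  got <- outcomes_table(rep)
  cats <- got$category[match(names(exp$per_record), got$record_id)]
  diffs <- character(0)
  if (!identical(cats, unname(unlist(exp$per_record))))
    diffs <- c(diffs, paste0("per-record categories: got ",
                             paste(cats, collapse = ","), " expected ",
                             paste(unlist(exp$per_record),
                                   collapse = ",")))
  for (f in c("pct_correct", "pct_incorrect", "pct_ambiguous",
              "pct_nomatch", "species_correct_pct", "true_species_pct"))
    if (abs(rep[[f]] - exp[[f]]) > 1e-9)
      diffs <- c(diffs, sprintf("%s: got %.10g expected %.10g",
                                f, rep[[f]], exp[[f]]))
  diffs
}

.verify_toy_abgd <- function() {
  ds <- load_fixture("toy_abgd")
  exp <- jsonlite::read_json(fixture_path("toy_abgd_expected.json"),
                             simplifyVector = TRUE)
  dm <- distance_matrix(ds, exp$model)
  parts <- abgd_scan(dm, exp$p_min, exp$p_max, exp$steps, exp$X)
  sel <- select_initial_partition(parts)
  cats <- categorize_groups(sel, ds)
  diffs <- character(0)
  if (length(sel$groups) != exp$n_groups)
    diffs <- c(diffs, sprintf("n_groups: got %d expected %d",
                              length(sel$groups), exp$n_groups))
  if (!identical(sort(cats$tags), sort(exp$tags)))
    diffs <- c(diffs, paste0("tags: got ",
                             paste(cats$tags, collapse = ",")))
  if (abs(cats$true_species_pct - exp$true_species_pct) > 1e-9)
    diffs <- c(diffs, sprintf("true_species_pct: got %.10g",
                              cats$true_species_pct))
  diffs
}

#' Verify the shipped fixtures against their stored expected outputs
#'
#' Recomputes every fixture's expected output through the public API and
#' compares against the stored payload.
#'
#' @return A data.frame with `fixture`, `pass` and `detail` (named diff
#'   on mismatch).
#' @export
verify_fixtures <- function() {
  checks <- list(toy_bm = .verify_toy_bm, toy_abgd = .verify_toy_abgd)
  rows <- lapply(names(checks), function(nm) {
    diffs <- checks[[nm]]()
    data.frame(fixture = nm, pass = length(diffs) == 0L,
               detail = paste(diffs, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
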