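# End-to-end orchestration of the comparative workflow: curate, then the
# alignment path (distances -> identification criteria + barcode-gap
# partitioning) and the alignment-free path (featurize -> cross-validated
# classifiers -> corrected t-test ranking), with all reports written as
# TSV/JSON.

#' Run the unsupervised (alignment-based) path
#'
#' Distance matrix, the three identification criteria, and the
#' barcode-gap partition scan with group categorisation.
#'
#' @param ds an aligned `BarcodeDataset`.
#' @param model distance model (`"simple"`, `"jc69"`, `"k80"`).
#' @param threshold numeric distance ceiling or `"percentile:<q>"`.
#' @param p_min,p_max,steps,X barcode-gap scan settings.
#' @param out_dir optional directory to write `identification_*.tsv`,
#'   `abgd_scan.tsv`, `abgd_groups.tsv` and `unsupervised.json`.
#' @return A list with `identification` (per-criterion
#'   `IdentificationReport`s), `partitions`, `selected_partition`,
#'   `selected_categories` and `abgd_table`.
#' @export
run_unsupervised <- function(ds, model = "simple", threshold = 0.03,
                             p_min = 0.001, p_max = 0.1, steps = 10,
                             X = 1.5, out_dir = NULL) {
  if (n_records(ds) == 0L) stop("empty dataset")
  dm <- distance_matrix(ds, model)
  idents <- lapply(c(BM = "BM", BCM = "BCM", ASB = "ASB"), function(cr)
    identify_dataset(dm, ds, cr, threshold = threshold))
  parts <- abgd_scan(dm, p_min, p_max, steps, X)
  sel <- select_initial_partition(parts)
  cats <- categorize_groups(sel, ds)
  tab <- abgd_summary(parts, ds)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cr in names(idents))
      utils::write.table(outcomes_table(idents[[cr]]),
                         file.path(out_dir,
                                   sprintf("identification_%s.tsv", cr)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tab, file.path(out_dir, "abgd_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    groups_df <- data.frame(
      record_id = unlist(sel$groups),
      group = rep(seq_along(sel$groups), lengths(sel$groups)),
      tag = rep(cats$tags, lengths(sel$groups)),
      stringsAsFactors = FALSE)
    utils::write.table(groups_df, file.path(out_dir, "abgd_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- list(
      model = model,
      identification = lapply(idents, function(r)
        r[c("criterion", "threshold", "pct_correct", "pct_incorrect",
            "pct_ambiguous", "pct_nomatch", "species_correct_pct",
            "true_species_pct")]),
      abgd = list(selected_prior = sel$prior_p,
                  n_groups = length(sel$groups),
                  pct_sequences = as.list(cats$pct_sequences),
                  true_species_pct = cats$true_species_pct))
    jsonlite::write_json(summary, file.path(out_dir, "unsupervised.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  list(identification = idents, partitions = parts,
       selected_partition = sel, selected_categories = cats,
       abgd_table = tab)
}

#' Run the supervised (classification) path
#'
#' Three stages: (1) screen the classifier line-up by repeated CV and
#' rank with the corrected paired t-test; (2) grid the k-mer length and
#' neighbour count of the nearest-neighbour classifier over the chosen
#' featurisation scheme; (3) re-evaluate the best grid cell (highest
#' accuracy; ties to smaller k, then smaller NN).
#'
#' @param ds a `BarcodeDataset` (raw sequences; gaps are stripped by the
#'   featurizers).
#' @param scheme alignment-free scheme for stages 2-3: `"spectrum"`,
#'   `"gappy"` or `"mismatch"`.
#' @param g,m gappy/mismatch parameters.
#' @param ks k-mer lengths for the stage-2 grid.
#' @param nns neighbour counts for the stage-2 grid.
#' @param classifiers named list of [classifier_spec()]s for stage 1
#'   (default: 1-NN, tree ensemble, ridge multinomial logistic).
#' @param screen_k k-mer length used for stage-1 screening.
#' @param n_folds,repeats,seed CV schedule.
#' @param out_dir optional directory for `stage1_ranking.tsv`,
#'   `stage2_grid.tsv`, `stage3_per_class.tsv` and `supervised.json`.
#' @return A list with `stage1` (ranking data.frame), `stage2` (grid
#'   data.frame), `best` (selected k/NN), `stage3` (final `CVResult`).
#' @export
run_supervised <- function(ds, scheme = c("spectrum", "gappy", "mismatch"),
                           g = 1, m = 1, ks = 2:6, nns = c(1, 3, 5),
                           classifiers = NULL, screen_k = 4,
                           n_folds = 10, repeats = 1, seed = 1,
                           out_dir = NULL) {
  scheme <- match.arg(scheme)
  if (n_records(ds) == 0L) stop("empty dataset")
  featurize <- function(k) switch(scheme,
    spectrum = spectrum_features(ds, k),
    gappy = gappy_features(ds, k, g),
    mismatch = mismatch_features(ds, k, m))
  classifiers <- classifiers %||% list(
    knn1 = classifier_spec("nearest-neighbor", nn = 1, seed = seed),
    rf = classifier_spec("tree-ensemble", n_trees = 100, seed = seed),
    mcc = classifier_spec("multinomial-logistic", seed = seed))
  fm_screen <- featurize(screen_k)
  stage1_cv <- lapply(classifiers, function(sp)
    evaluate_cv(fm_screen, sp, n_folds, repeats, seed))
  stage1 <- rank_classifiers(lapply(stage1_cv, `[[`, "fold_scores"),
                             test_train_ratio = 1 / (n_folds - 1))
  grid <- expand.grid(k = ks, nn = nns)
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    fm <- featurize(grid$k[i])
    sp <- classifier_spec("nearest-neighbor", nn = grid$nn[i],
                          seed = seed)
    cv <- evaluate_cv(fm, sp, n_folds, repeats, seed)
    data.frame(k = grid$k[i], nn = grid$nn[i],
               accuracy_pct = cv$accuracy_pct, rmse = cv$rmse,
               species_all_correct_pct = cv$species_all_correct_pct)
  })
  stage2 <- do.call(rbind, cells)
  ord <- order(-stage2$accuracy_pct, stage2$k, stage2$nn)
  best <- stage2[ord[1L], ]
  fm_best <- featurize(best$k)
  stage3 <- evaluate_cv(fm_best,
                        classifier_spec("nearest-neighbor", nn = best$nn,
                                        seed = seed),
                        n_folds, repeats, seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(stage1, file.path(out_dir, "stage1_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(stage2, file.path(out_dir, "stage2_grid.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(stage3$per_class,
                       file.path(out_dir, "stage3_per_class.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(scheme = scheme,
           stage1 = stage1,
           best = list(k = best$k, nn = best$nn),
           stage3 = stage3[c("accuracy_pct", "rmse",
                             "species_any_correct_pct",
                             "species_all_correct_pct",
                             "tpr1_species_pct")]),
      file.path(out_dir, "supervised.json"),
      auto_unbox = TRUE, digits = 10, pretty = TRUE, dataframe = "rows")
  }
  list(stage1 = stage1, stage1_cv = stage1_cv, stage2 = stage2,
       best = list(k = best$k, nn = best$nn), stage3 = stage3)
}

#' Read a flat key-value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment; comma-separated
#' values become vectors; numbers are coerced.
#'
#' @param path configuration file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    cfg[[key]] <- if (!anyNA(num)) num else vals
  }
  cfg
}

#' Run the full comparative workflow
#'
#' Curates the input (length and conspecific filters), runs the
#' unsupervised path on the aligned data and the supervised path on the
#' alignment-free data, and writes `report.json` plus `tables/*.tsv`
#' under `out_dir`. Fully deterministic under a fixed seed: two runs with
#' the same configuration produce byte-identical outputs.
#'
#' @param config a named list (or path to a file for
#'   [read_run_config()]). Recognised keys: `fasta` + `marker` (or
#'   `synthetic = 1` with generator settings `n_species`, `members`,
#'   `seq_length`, `intra`, `inter`, `singletons`), `min_length`,
#'   `min_conspecifics`, `model`, `threshold`, `pmin`, `pmax`, `steps`,
#'   `gap_width`, `scheme`, `ks`, `nns`, `folds`, `repeats`, `seed`.
#' @param out_dir output directory.
#' @return Invisibly, a list with the unsupervised and supervised results
#'   and the path of the JSON report.
#' @export
run_workflow <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- as.integer(config$seed %||% 1)
  if (!is.null(config$fasta)) {
    ds <- read_barcode_fasta(config$fasta,
                             marker = config$marker %||% "marker",
                             aligned = TRUE)
  } else {
    ds <- generate_dataset(
      n_species = config$n_species %||% 20,
      members_per_species = config$members %||% 4,
      seq_length = config$seq_length %||% 600,
      intra_divergence = config$intra %||% 0.005,
      inter_divergence = config$inter %||% 0.08,
      singleton_fraction = config$singletons %||% 0,
      indel_rate = config$indel_rate %||% 0,
      missing_rate = config$missing_rate %||% 0,
      seed = seed)$dataset
  }
  if (n_records(ds) == 0L) stop("empty dataset: nothing to analyse")
  if (!is.null(config$min_length))
    ds <- filter_min_length(ds, config$min_length)
  if (!is.null(config$min_conspecifics))
    ds <- filter_min_conspecifics(ds, config$min_conspecifics)
  if (n_records(ds) == 0L) stop("curation removed every record")
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  tdir <- file.path(out_dir, "tables")
  t0 <- proc.time()[["elapsed"]]
  unsup <- run_unsupervised(
    ds, model = config$model %||% "simple",
    threshold = config$threshold %||% 0.03,
    p_min = config$pmin %||% 0.001, p_max = config$pmax %||% 0.1,
    steps = config$steps %||% 10, X = config$gap_width %||% 1.5,
    out_dir = tdir)
  t1 <- proc.time()[["elapsed"]]
  message(sprintf("unsupervised path: %.1f s", t1 - t0))
  sup <- run_supervised(
    ds, scheme = config$scheme %||% "spectrum",
    ks = config$ks %||% 2:6, nns = config$nns %||% c(1, 3, 5),
    n_folds = config$folds %||% 10, repeats = config$repeats %||% 1,
    seed = seed, out_dir = tdir)
  message(sprintf("supervised path: %.1f s",
                  proc.time()[["elapsed"]] - t1))
  report <- list(
    dataset = dataset_summary(ds)[c("n_sequences", "n_species",
                                    "n_singletons")],
    seed = seed,
    unsupervised = list(
      identification = lapply(unsup$identification, function(r)
        r[c("criterion", "threshold", "pct_correct", "pct_incorrect",
            "pct_ambiguous", "pct_nomatch", "species_correct_pct",
            "true_species_pct")]),
      abgd = list(selected_prior = unsup$selected_partition$prior_p,
                  n_groups = length(unsup$selected_partition$groups),
                  true_species_pct =
                    unsup$selected_categories$true_species_pct)),
    supervised = list(
      best = sup$best,
      accuracy_pct = sup$stage3$accuracy_pct,
      rmse = sup$stage3$rmse,
      species_all_correct_pct = sup$stage3$species_all_correct_pct,
      tpr1_species_pct = sup$stage3$tpr1_species_pct))
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  invisible(list(unsupervised = unsup, supervised = sup,
                 report = report_path))
}
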