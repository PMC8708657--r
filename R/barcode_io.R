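#' Construct a barcode dataset
#'
#' A `BarcodeDataset` is the package's container for a species-labelled
#' barcode reference library: one row per sequence, with a unique accession
#' (`record_id`), a species label, and the nucleotide string. Aligned
#' datasets must have uniform sequence length.
#'
#' @param record_id character vector of unique accession ids.
#' @param species character vector of species labels (binomials).
#' @param sequence character vector of nucleotide strings over
#'   `A,C,G,T,-,N` and IUPAC ambiguity codes. Uppercased; `U` mapped to `T`.
#' @param marker marker name, e.g. `"rbcL"`.
#' @param aligned logical; if `TRUE` all sequences must have equal length.
#' @return An object of class `BarcodeDataset`.
#' @export
barcode_dataset <- function(record_id, species, sequence,
                            marker = "marker", aligned = FALSE) {
  record_id <- as.character(record_id)
  species <- as.character(species)
  sequence <- chartr("u", "t", toupper(as.character(sequence)))
  sequence <- chartr("U", "T", sequence)
  n <- length(record_id)
  if (length(species) != n || length(sequence) != n)
    stop("record_id, species and sequence must have equal length")
  if (n > 0) {
    if (any(!nzchar(sequence)))
      stop("sequences must be non-empty")
    if (any(!nzchar(species)))
      stop("species labels must be non-empty")
    dup <- record_id[duplicated(record_id)]
    if (length(dup))
      stop("duplicate record ids: ", paste(unique(dup), collapse = ", "))
    if (aligned && length(unique(nchar(sequence))) > 1L)
      stop("aligned dataset requires uniform sequence length")
  }
  structure(
    list(records = data.frame(record_id = record_id, species = species,
                              sequence = sequence,
                              stringsAsFactors = FALSE),
         marker = marker, aligned = aligned),
    class = "BarcodeDataset")
}

#' @export
print.BarcodeDataset <- function(x, ...) {
  cat(sprintf("BarcodeDataset: %d sequences, %d species, marker '%s'%s\n",
              n_records(x), length(unique(x$records$species)), x$marker,
              if (x$aligned) sprintf(", aligned (L=%d)",
                                     if (n_records(x)) nchar(x$records$sequence[1]) else 0L)
              else ""))
  invisible(x)
}

#' Number of records in a dataset
#' @param ds a `BarcodeDataset`.
#' @return integer count.
#' @export
n_records <- function(ds) nrow(ds$records)

#' Header parsing rule for labelled FASTA
#'
#' Barcode FASTA headers carry both an accession and a species label but
#' repositories disagree on the layout. A `label_spec` names the field
#' separator and, in order, which fields are the species and the accession.
#' The default expects `Species_name|ACCESSION` (underscores inside the
#' species token, `|` between fields).
#'
#' @param fields character vector naming the header fields in order; must
#'   contain `"species"` and `"id"` (other names are ignored filler).
#' @param delim single-character field separator.
#' @return A `label_spec` list.
#' @export
label_spec <- function(fields = c("species", "id"), delim = "|") {
  if (!all(c("species", "id") %in% fields))
    stop("label_spec fields must include 'species' and 'id'")
  structure(list(fields = fields, delim = delim), class = "label_spec")
}

#' Read a species-labelled barcode FASTA file
#'
#' @param path path to a FASTA file.
#' @param marker marker name recorded on the dataset.
#' @param spec a [label_spec()] describing the header layout.
#' @param aligned logical; declare the file as aligned (uniform length
#'   enforced).
#' @return A `BarcodeDataset`; entry order is preserved and sequences are
#'   uppercased with `U` mapped to `T`.
#' @export
read_barcode_fasta <- function(path, marker = "marker",
                               spec = label_spec(), aligned = FALSE) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    return(barcode_dataset(character(), character(), character(),
                           marker = marker, aligned = aligned))
  headers <- names(set)
  parts <- strsplit(headers, spec$delim, fixed = TRUE)
  nf <- length(spec$fields)
  bad <- vapply(parts, length, 1L) < nf
  if (any(bad))
    stop("FASTA header(s) not matching label spec (expected ", nf,
         " '", spec$delim, "'-separated fields): ",
         paste(headers[bad], collapse = "; "))
  field <- function(name) {
    i <- match(name, spec$fields)
    vapply(parts, function(p) trimws(p[[i]]), character(1))
  }
  barcode_dataset(field("id"), field("species"),
                  as.character(set), marker = marker, aligned = aligned)
}

#' Write a barcode dataset to FASTA
#'
#' Headers are rebuilt from the dataset using `spec` (species and accession
#' joined by the delimiter, in the declared field order).
#'
#' @inheritParams read_barcode_fasta
#' @param ds a `BarcodeDataset`.
#' @return `path`, invisibly.
#' @export
write_barcode_fasta <- function(ds, path, spec = label_spec()) {
  vals <- list(species = ds$records$species, id = ds$records$record_id)
  cols <- lapply(spec$fields, function(f) vals[[f]] %||%
                   rep("", n_records(ds)))
  headers <- do.call(paste, c(cols, sep = spec$delim))
  set <- Biostrings::BStringSet(ds$records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Ungapped length: informative bases only (gaps and N excluded).
ungapped_length <- function(sequence) {
  nchar(gsub("[-N]", "", sequence))
}

#' Keep only standard-length barcodes
#'
#' Retains records whose ungapped length (non-gap, non-N characters)
#' strictly exceeds `min_len`; the conventional curation rule keeps
#' sequences of more than 400 bp.
#'
#' @param ds a `BarcodeDataset`.
#' @param min_len minimum length; strict `>` comparison.
#' @return The filtered `BarcodeDataset` (order preserved).
#' @export
filter_min_length <- function(ds, min_len = 400) {
  stopifnot(min_len >= 1)
  keep <- ungapped_length(ds$records$sequence) > min_len
  subset_dataset(ds, keep)
}

#' Keep only species with enough conspecific records
#'
#' Species represented by fewer than `min_n` sequences are removed
#' entirely; the standardising curation used for reference libraries keeps
#' species with at least three individuals.
#'
#' @param ds a `BarcodeDataset`.
#' @param min_n minimum number of records per species.
#' @return The filtered `BarcodeDataset`.
#' @export
filter_min_conspecifics <- function(ds, min_n = 3) {
  stopifnot(min_n >= 1)
  counts <- table(ds$records$species)
  keep <- counts[ds$records$species] >= min_n
  subset_dataset(ds, as.vector(keep))
}

#' Restrict two marker datasets to their common species
#'
#' @param ds1,ds2 `BarcodeDataset`s for two markers.
#' @return A list of the two datasets, each restricted to species present
#'   in both inputs.
#' @export
intersect_markers <- function(ds1, ds2) {
  common <- intersect(unique(ds1$records$species),
                      unique(ds2$records$species))
  list(subset_dataset(ds1, ds1$records$species %in% common),
       subset_dataset(ds2, ds2$records$species %in% common))
}

subset_dataset <- function(ds, keep) {
  barcode_dataset(ds$records$record_id[keep], ds$records$species[keep],
                  ds$records$sequence[keep], marker = ds$marker,
                  aligned = ds$aligned)
}

#' Summarise a barcode dataset
#'
#' @param ds a `BarcodeDataset`.
#' @return A list with `n_sequences`, `n_species`, `n_singletons`
#'   (species with exactly one record) and `per_species` (a table of
#'   members-per-species counts: how many species have 1, 2, ... records).
#' @export
dataset_summary <- function(ds) {
  sp <- ds$records$species
  counts <- table(sp)
  list(n_sequences = n_records(ds),
       n_species = length(counts),
       n_singletons = sum(counts == 1L),
       per_species = table(as.integer(counts)))
}
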