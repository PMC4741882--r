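# Readers and writers for the plain-text interchange formats of the
# pipeline: wide Ct tables (samples x systems), annotation TSV, 0/1
# presence matrices, BED peak files and ground-truth JSON.

#' Write / read a wide Ct table
#'
#' Rows are samples, columns assay systems. Ct values are written rounded
#' to 2 decimals (the reporting convention; internal arithmetic stays at
#' full precision).
#'
#' @param ct_tbl long tibble `sample`, `system`, `ct`.
#' @param path file path.
#' @return `write_ct_table()` returns `path` invisibly; `read_ct_table()` a
#'   long tibble `sample`, `system`, `ct`.
#' @export
write_ct_table <- function(ct_tbl, path) {
  assert_columns(ct_tbl, c("sample", "system", "ct"), "ct_tbl")
  wide <- ct_tbl |>
    mutate(ct = round(.data$ct, 2)) |>
    select("sample", "system", "ct") |>
    tidyr::pivot_wider(names_from = "system", values_from = "ct")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    tidyr::pivot_longer(-"sample", names_to = "system", values_to = "ct")
}

#' Write / read the sample annotation table
#'
#' @param annotations annotation tibble (see [simulate_cohort()]).
#' @param path file path.
#' @export
write_annotations <- function(annotations, path) {
  assert_columns(annotations, c("sample", "patient", "tissue_class", "cohort"),
                 "annotations")
  readr::write_tsv(annotations, path)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write / read a loci-by-species presence matrix
#'
#' Wide 0/1 TSV with loci as rows and species as columns.
#'
#' @param presence long tibble `locus`, `species`, `present` (a `category`
#'   column, if present, is written as the second column).
#' @param path file path.
#' @export
write_presence <- function(presence, path) {
  assert_columns(presence, c("locus", "species", "present"), "presence")
  id_cols <- intersect(c("locus", "category"), names(presence))
  wide <- presence |>
    mutate(present = as.integer(.data$present)) |>
    select(dplyr::all_of(id_cols), "species", "present") |>
    tidyr::pivot_wider(names_from = "species", values_from = "present")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_presence
#' @export
read_presence <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  id_cols <- intersect(c("locus", "category"), names(wide))
  wide |>
    tidyr::pivot_longer(-dplyr::all_of(id_cols),
                        names_to = "species", values_to = "present") |>
    mutate(present = as.logical(.data$present))
}

#' Write / read BED interval files
#'
#' 3-6 column BED, 0-based half-open. `read_bed()` names whatever columns
#' are present `chrom`, `start`, `end`, `name`, `score`, `strand`.
#'
#' @param intervals tibble with at least `chrom`, `start`, `end`.
#' @param path file path.
#' @export
write_bed <- function(intervals, path) {
  assert_columns(intervals, c("chrom", "start", "end"), "intervals")
  if ("strand" %in% names(intervals) && !"score" %in% names(intervals)) {
    intervals$score <- 0 # BED requires the score column before strand
  }
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  readr::write_tsv(intervals[cols], path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  if (ncol(raw) < 3L) abort("BED files need at least 3 columns")
  names(raw) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(6, ncol(raw)))]
  raw
}

#' Export a simulated cohort to a directory
#'
#' Writes the Ct table, annotations and per-reaction ground truth (JSON) as
#' the plain-text bundle a downstream analysis would consume.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "herv_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_ct_table(cohort$ct, file.path(dir, "ct_table.tsv"))
  write_annotations(cohort$annotations, file.path(dir, "annotations.tsv"))
  jsonlite::write_json(
    cohort$truth$reactions, file.path(dir, "ground_truth.json"),
    digits = NA
  )
  invisible(dir)
}
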