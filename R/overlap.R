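#' Overlap of a genomic interval with a peak set
#'
#' Total number of bases the query interval shares with the union of the
#' peaks (overlapping peaks are merged first, so no base is counted twice),
#' using BED conventions: 0-based, half-open, strand-agnostic, chromosome
#' names compared literally.
#'
#' @param query a one-row data frame or list with `chrom`, `start`, `end`.
#' @param peaks tibble of intervals with `chrom`, `start`, `end`.
#' @return A list with `bases` (integer) and `hit` (`bases > 0`).
#' @examples
#' interval_overlap(
#'   list(chrom = "chr1", start = 100, end = 200),
#'   tibble::tibble(chrom = "chr1", start = 150, end = 250)
#' )
#' @export
interval_overlap <- function(query, peaks) {
  q <- validate_interval(query)
  if (nrow(peaks) > 0L) {
    assert_columns(peaks, c("chrom", "start", "end"), "peaks")
    if (any(peaks$start < 0) || any(peaks$start >= peaks$end)) {
      abort("malformed peak interval: need 0 <= start < end")
    }
  }
  same <- peaks[peaks$chrom == q$chrom, , drop = FALSE]
  if (nrow(same) == 0L) return(list(bases = 0L, hit = FALSE))
  # half-open [start, end) -> closed IRanges [start + 1, end]
  merged <- IRanges::reduce(IRanges::IRanges(same$start + 1L, same$end))
  inter <- IRanges::intersect(merged, IRanges::IRanges(q$start + 1L, q$end))
  bases <- sum(IRanges::width(inter))
  list(bases = as.integer(bases), hit = bases > 0L)
}

validate_interval <- function(query) {
  q <- as.list(query)[c("chrom", "start", "end")]
  if (any(vapply(q, is.null, logical(1)))) {
    abort("`query` needs chrom, start and end")
  }
  if (!is.finite(q$start) || !is.finite(q$end) || q$start < 0 || q$start >= q$end) {
    abort("malformed interval: need 0 <= start < end")
  }
  q
}

#' Mean histone-mark overlap scores for LTR intervals
#'
#' For every locus and mark, the fraction of the LTR covered by that mark's
#' peaks is computed per cell line (overlapping bases divided by LTR
#' length, in `[0, 1]`) and averaged over the cell lines with data for the
#' mark. Marks without any peak data are dropped with a warning.
#'
#' @param ltr tibble of LTR intervals: `locus`, `chrom`, `start`, `end`.
#' @param peaks long peak tibble: `mark`, `cell_line`, `chrom`, `start`,
#'   `end` (as from [simulate_peak_sets()] or [read_bed()] files bound
#'   together).
#' @param marks optional character vector of expected marks; marks with no
#'   peak data are dropped from the result with a warning.
#' @return A tibble of class `herv_overlap` with `locus`, `mark`, `score`
#'   (mean over cell lines), `n_cell_lines`; the per-cell-line layer is
#'   kept in attribute `by_cell_line`.
#' @export
mean_mark_overlap <- function(ltr, peaks, marks = NULL) {
  assert_columns(ltr, c("locus", "chrom", "start", "end"), "ltr")
  assert_columns(peaks, c("mark", "cell_line", "chrom", "start", "end"), "peaks")
  if (any(ltr$start < 0) || any(ltr$start >= ltr$end)) {
    abort("malformed LTR interval: need 0 <= start < end")
  }
  if (!is.null(marks)) {
    absent <- setdiff(marks, unique(peaks$mark))
    if (length(absent) > 0L) {
      warn(sprintf("no peak data for mark(s), dropped: %s", paste(absent, collapse = ", ")))
    }
    peaks <- peaks |> filter(.data$mark %in% marks)
  }
  by_cell_line <- tidyr::crossing(
    ltr |> select("locus", "chrom", "start", "end"),
    peaks |> distinct(.data$mark, .data$cell_line)
  ) |>
    mutate(score = purrr::pmap_dbl(
      list(.data$chrom, .data$start, .data$end, .data$mark, .data$cell_line),
      function(chrom, start, end, mark, cell_line) {
        pk <- peaks[peaks$mark == mark & peaks$cell_line == cell_line, ]
        ov <- interval_overlap(list(chrom = chrom, start = start, end = end), pk)
        ov$bases / (end - start)
      }
    )) |>
    select("locus", "mark", "cell_line", "score")
  out <- by_cell_line |>
    group_by(.data$locus, .data$mark) |>
    summarise(
      score = mean(.data$score), n_cell_lines = dplyr::n(), .groups = "drop"
    )
  attr(out, "by_cell_line") <- by_cell_line
  class(out) <- c("herv_overlap", class(out))
  out
}

#' Compare activating / repressive mark scores between locus categories
#'
#' Summarizes each locus by its mean score over the activating marks (and,
#' separately, the repressive marks) and contrasts the case category
#' against the pooled control categories with the rank-sum test of
#' [rank_sum_test()].
#'
#' @param scores output of [mean_mark_overlap()].
#' @param categories tibble with `locus`, `category`.
#' @param activating,repressive mark sets (defaults
#'   [activating_marks()] / [repressive_marks()]).
#' @param case_category category tested for enrichment (default
#'   `"crc_specific"`).
#' @param control_categories categories pooled as the comparison group.
#' @return A tibble `mark_class`, `marks`, `n_case`, `n_control`,
#'   `median_case`, `median_control`, `statistic`, `p_value`, `stars`.
#' @export
mark_class_enrichment <- function(scores, categories,
                                  activating = activating_marks(),
                                  repressive = repressive_marks(),
                                  case_category = "crc_specific",
                                  control_categories = c("silent", "constitutive")) {
  assert_columns(scores, c("locus", "mark", "score"), "scores")
  assert_columns(categories, c("locus", "category"), "categories")
  sets <- list(activating = activating, repressive = repressive)
  purrr::imap(sets, function(marks, cls) {
    marks_present <- intersect(marks, unique(scores$mark))
    if (length(marks_present) == 0L) {
      abort(sprintf("no %s marks present in the score matrix", cls))
    }
    per_locus <- scores |>
      filter(.data$mark %in% marks_present) |>
      group_by(.data$locus) |>
      summarise(value = mean(.data$score), .groups = "drop") |>
      inner_join(categories, by = "locus")
    x <- per_locus$value[per_locus$category == case_category]
    y <- per_locus$value[per_locus$category %in% control_categories]
    if (length(x) == 0L || length(y) == 0L) {
      abort(sprintf("empty category group in %s-mark comparison", cls))
    }
    rs <- rank_sum_test(x, y)
    tibble(
      mark_class = cls, marks = paste(marks_present, collapse = ","),
      n_case = length(x), n_control = length(y),
      median_case = median(x), median_control = median(y),
      statistic = rs$statistic, p_value = rs$p_value
    )
  }) |>
    list_rbind() |>
    mutate(stars = p_stars(.data$p_value))
}
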