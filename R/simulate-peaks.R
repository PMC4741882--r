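#' Histone marks and default activating/repressive partitions
#'
#' The twelve histone modifications scored against proviral 5' LTRs. The
#' activating set (promoter/enhancer-associated acetylation and H3K4
#' methylation plus H2A.Z) and repressive set (H3K9me3/H3K27me3
#' heterochromatin marks) are configuration defaults following standard
#' chromatin biology; both are plain character vectors and can be replaced.
#'
#' @return Character vector of mark names.
#' @export
encode_marks <- function() {
  c(
    "H2az", "H3k4me1", "H3k4me2", "H3k4me3", "H3k9ac", "H3k27ac",
    "H3k79me2", "H3k9me3", "H3k27me3", "H3k9me1", "H3k36me3", "H4k20me1"
  )
}

#' @rdname encode_marks
#' @export
activating_marks <- function() {
  c("H2az", "H3k4me1", "H3k4me2", "H3k4me3", "H3k9ac", "H3k27ac")
}

#' @rdname encode_marks
#' @export
repressive_marks <- function() {
  c("H3k9me3", "H3k27me3")
}

#' Simulate 5' LTR intervals for a locus set
#'
#' Places each locus at a random position (0-based, half-open coordinates)
#' with LTR lengths around 450 bp, the typical length of an HERV-H long
#' terminal repeat.
#'
#' @param loci tibble with columns `locus`, `category`.
#' @param mean_length,sd_length LTR length distribution (bp).
#' @param seed optional integer seed.
#' @return A tibble with columns `locus`, `category`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
simulate_ltr_intervals <- function(loci = default_loci(), mean_length = 450,
                                   sd_length = 50, seed = NULL) {
  assert_columns(loci, c("locus", "category"), "loci")
  with_seed(seed, {
    n <- nrow(loci)
    len <- pmax(200L, as.integer(round(rnorm(n, mean_length, sd_length))))
    start <- as.integer(round(runif(n, 1e5, 1e8)))
    loci |>
      mutate(
        chrom = paste0("chr", sample(c(1:22, "X"), n, replace = TRUE)),
        start = start, end = start + len,
        strand = sample(c("+", "-"), n, replace = TRUE)
      )
  })
}

#' Simulate histone-mark peak sets around LTR intervals
#'
#' For every (mark, cell line, locus) triple a peak overlapping the LTR is
#' emitted with probability `enrichment` when the locus is CRC-specific and
#' the mark is in the activating set, and with probability `background`
#' otherwise. Non-overlapping decoy peaks are added per cell line so that
#' peak files are not trivially co-located with the loci. Peaks use BED
#' conventions (0-based, half-open).
#'
#' @param ltr tibble as [simulate_ltr_intervals()].
#' @param marks,cell_lines character vectors of marks and cell lines.
#' @param enrichment,background overlap probabilities in `[0, 1]`.
#' @param activating marks treated as activating for the enrichment rule.
#' @param enriched_category locus category receiving `enrichment`.
#' @param n_decoys decoy (non-overlapping) peaks per mark and cell line.
#' @param seed optional integer seed.
#' @return A list of class `herv_peaksim`: `peaks` (tibble `mark`,
#'   `cell_line`, `chrom`, `start`, `end`, `name`) and `truth` (tibble
#'   `locus`, `mark`, `cell_line`, `hit`, `p_hit`).
#' @export
simulate_peak_sets <- function(ltr,
                               marks = encode_marks(),
                               cell_lines = c("HCT116", "Caco2", "HepG2"),
                               enrichment = 0.9, background = 0.1,
                               activating = activating_marks(),
                               enriched_category = "crc_specific",
                               n_decoys = 20, seed = NULL) {
  assert_columns(ltr, c("locus", "category", "chrom", "start", "end"), "ltr")
  if (any(ltr$start < 0) || any(ltr$start >= ltr$end)) {
    abort("malformed LTR interval: need 0 <= start < end")
  }
  assert_probability(c(enrichment, background), "enrichment")
  with_seed(seed, {
    grid <- tidyr::crossing(ltr, mark = marks, cell_line = cell_lines) |>
      mutate(
        p_hit = ifelse(
          .data$category == enriched_category & .data$mark %in% activating,
          enrichment, background
        ),
        hit = runif(dplyr::n()) < .data$p_hit
      )
    hits <- grid |> filter(.data$hit)
    n <- nrow(hits)
    peaks_hit <- NULL
    if (n > 0L) {
      width <- as.integer(round(runif(n, 200, 1000)))
      # anchor each peak so it overlaps its LTR by at least one base
      pk_start <- as.integer(round(runif(
        n,
        pmax(0, hits$start - width + 1L), hits$end - 1L
      )))
      peaks_hit <- hits |>
        transmute(
          .data$mark, .data$cell_line, .data$chrom,
          start = pk_start, end = pk_start + width,
          name = paste0(.data$mark, "_", .data$cell_line, "_", .data$locus)
        )
    }
    decoys <- tidyr::crossing(
      mark = marks, cell_line = cell_lines, i = seq_len(n_decoys)
    )
    nd <- nrow(decoys)
    dstart <- as.integer(round(runif(nd, 2e8, 3e8))) # beyond any simulated LTR
    peaks_decoy <- decoys |>
      transmute(
        .data$mark, .data$cell_line,
        chrom = paste0("chr", sample(c(1:22, "X"), nd, replace = TRUE)),
        start = dstart,
        end = dstart + as.integer(round(runif(nd, 200, 1000))),
        name = paste0(.data$mark, "_", .data$cell_line, "_decoy", .data$i)
      )
    structure(
      list(
        peaks = bind_rows(peaks_hit, peaks_decoy) |>
          arrange(.data$mark, .data$cell_line, .data$chrom, .data$start),
        truth = grid |> select("locus", "mark", "cell_line", "hit", "p_hit")
      ),
      class = "herv_peaksim"
    )
  })
}
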