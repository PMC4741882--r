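# interval arithmetic, peak simulation and mark-class enrichment

test_that("interval overlap counts shared bases in half-open coordinates", {
  got <- interval_overlap(
    list(chrom = "chr1", start = 100, end = 200),
    tibble::tibble(chrom = "chr1", start = 150, end = 250)
  )
  expect_equal(got$bases, 50L)
  expect_true(got$hit)
  disjoint <- interval_overlap(
    list(chrom = "chr1", start = 100, end = 200),
    tibble::tibble(chrom = "chr1", start = 200, end = 300)
  )
  expect_equal(disjoint$bases, 0L)
  expect_false(disjoint$hit)
  other_chrom <- interval_overlap(
    list(chrom = "chr1", start = 100, end = 200),
    tibble::tibble(chrom = "chr2", start = 100, end = 200)
  )
  expect_equal(other_chrom$bases, 0L)
  expect_error(
    interval_overlap(list(chrom = "chr1", start = 200, end = 100),
                     tibble::tibble(chrom = "chr1", start = 1, end = 2)),
    "malformed"
  )
})

test_that("interval overlap equals per-base brute force on random instances", {
  set.seed(71)
  for (rep in 1:200) {
    chrom_len <- 2000
    qs <- sample(0:(chrom_len - 50), 1)
    qe <- qs + sample(1:50, 1)
    n_pk <- sample(0:8, 1)
    starts <- sample(0:(chrom_len - 60), n_pk, replace = TRUE)
    ends <- starts + sample(1:60, max(1, n_pk), replace = TRUE)[seq_len(n_pk)]
    got <- interval_overlap(
      list(chrom = "c", start = qs, end = qe),
      tibble::tibble(chrom = rep("c", n_pk), start = starts, end = ends)
    )
    expect_equal(
      got$bases,
      oracle_overlap_bruteforce(qs, qe, starts, ends, chrom_len)
    )
  }
})

test_that("overlap is symmetric between query and a single peak", {
  set.seed(72)
  for (rep in 1:20) {
    a <- sort(sample(0:500, 2)); if (a[1] == a[2]) next
    b <- sort(sample(0:500, 2)); if (b[1] == b[2]) next
    ab <- interval_overlap(list(chrom = "c", start = a[1], end = a[2]),
                           tibble::tibble(chrom = "c", start = b[1], end = b[2]))
    ba <- interval_overlap(list(chrom = "c", start = b[1], end = b[2]),
                           tibble::tibble(chrom = "c", start = a[1], end = a[2]))
    expect_equal(ab$bases, ba$bases)
  }
})

test_that("mean mark overlap averages LTR coverage across cell lines", {
  ltr <- tibble::tibble(locus = "l1", chrom = "chr1", start = 1000, end = 1500)
  peaks <- tibble::tibble(
    mark = "H3k9ac", cell_line = c("A", "B"),
    chrom = "chr1", start = c(900, 5000), end = c(1600, 5200)
  )
  out <- mean_mark_overlap(ltr, peaks)
  expect_equal(out$score, 0.5) # full containment in A, nothing in B
  expect_equal(out$n_cell_lines, 2)
  by_cl <- tidy(out)
  expect_equal(sort(by_cl$score), c(0, 1))
  expect_warning(
    mean_mark_overlap(ltr, peaks, marks = c("H3k9ac", "H3k27ac")),
    "H3k27ac"
  )
  expect_true(all(out$score >= 0 & out$score <= 1))
})

test_that("peak simulation honors degenerate enrichment probabilities", {
  ltr <- simulate_ltr_intervals(seed = 73)
  all_hit <- simulate_peak_sets(ltr, enrichment = 1, background = 1, seed = 74)
  scores <- mean_mark_overlap(ltr, all_hit$peaks)
  expect_true(all(scores$score > 0))
  none <- simulate_peak_sets(ltr, enrichment = 0, background = 0, seed = 75)
  expect_true(all(!none$truth$hit))
  # with zero hit probability only decoys remain, which never overlap
  scores0 <- mean_mark_overlap(ltr, none$peaks)
  expect_true(all(scores0$score == 0))
  expect_error(simulate_peak_sets(ltr, enrichment = 1.5), "\\[0, 1\\]")
  bad <- ltr; bad$end[1] <- bad$start[1]
  expect_error(simulate_peak_sets(bad), "malformed")
})

test_that("overlap fractions follow the configured enrichment probability", {
  loci <- tibble::tibble(locus = sprintf("l%04d", 1:1000), category = "crc_specific")
  ltr <- simulate_ltr_intervals(loci, seed = 76)
  sim <- simulate_peak_sets(ltr, marks = "H3k9ac", cell_lines = "A",
                            enrichment = 0.5, background = 0, n_decoys = 0,
                            seed = 77)
  scores <- mean_mark_overlap(ltr, sim$peaks)
  hit_frac <- mean(scores$score > 0)
  expect_lt(abs(hit_frac - 0.5), 3 * sqrt(0.25 / 1000))
  expect_equal(scores$score > 0,
               sim$truth$hit[match(scores$locus, sim$truth$locus)])
})

test_that("activating-mark enrichment separates CRC-specific loci", {
  loci <- default_loci() |>
    dplyr::filter(category %in% c("crc_specific", "silent", "constitutive"))
  ltr <- simulate_ltr_intervals(loci, seed = 78)
  sim <- simulate_peak_sets(ltr, enrichment = 1, background = 0, seed = 79)
  scores <- mean_mark_overlap(ltr, sim$peaks)
  rep_out <- mark_class_enrichment(scores, loci)
  act <- rep_out[rep_out$mark_class == "activating", ]
  expect_equal(act$n_case, 14)
  expect_equal(act$n_control, 9)
  expect_lt(act$p_value, 0.01)
  expect_match(act$marks, "H3k9ac")
  expect_match(rep_out$marks[rep_out$mark_class == "repressive"], "H3k9me3")
  # identical scores in both groups: no separation
  flat <- scores |> dplyr::mutate(score = 0.5)
  flat_out <- mark_class_enrichment(flat, loci)
  expect_true(all(flat_out$p_value > 0.5))
})
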