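# insertion dating: coverage presence, flank orthology, age assignment,
# rank-sum machinery and category contrasts

test_that("coverage presence uses a >= threshold boundary", {
  cov <- tibble::tibble(
    locus = "l1", species = c("a", "b", "c"), coverage = c(0.9, 0.5, 0)
  )
  out <- presence_from_coverage(cov, min_coverage = 0.5)
  expect_equal(out$present, c(TRUE, TRUE, FALSE))
  cov$coverage[1] <- 1.2
  expect_error(presence_from_coverage(cov), "\\[0, 1\\]")
})

test_that("flank orthology compares ungapped identity against the cutoff", {
  set.seed(51)
  seqs <- c("A", "C", "G", "T")
  human <- paste(sample(seqs, 500, TRUE), collapse = "")
  expect_true(flank_orthology_check(human, human))
  expect_equal(attr(flank_orthology_check(human, human), "identity"), 1)
  # unrelated random DNA matches at about 1/4 of positions
  other <- paste(sample(seqs, 500, TRUE), collapse = "")
  res <- flank_orthology_check(human, other)
  expect_false(res)
  expect_lt(attr(res, "identity"), 0.4)
  # 10% point mutations leave ~90% identity, above the 0.7 default
  chars <- strsplit(human, "")[[1]]
  mut <- sample(500, 50)
  chars[mut] <- sample(seqs, 50, TRUE)
  res2 <- flank_orthology_check(human, paste(chars, collapse = ""))
  expect_true(res2)
  expect_equal(attr(res2, "identity"), 0.9, tolerance = 0.05)
  expect_error(flank_orthology_check("", human), "empty")
  expect_error(flank_orthology_check("ACGT", human), "at least 500")
})

test_that("gap and N positions are excluded from the identity computation", {
  a <- paste(rep("A", 500), collapse = "")
  b <- paste(c(rep("-", 250), rep("A", 250)), collapse = "")
  res <- flank_orthology_check(a, b)
  expect_equal(attr(res, "n_compared"), 250)
  expect_equal(attr(res, "identity"), 1)
})

test_that("ages come from the most distant species carrying the locus", {
  mk <- function(present_species) {
    tibble::tibble(
      locus = "l1", species = species_age_table()$species,
      present = species_age_table()$species %in% present_species
    )
  }
  young <- assign_age(mk(c("human", "chimp")))
  expect_equal(young$defining_species, "chimp")
  expect_equal(young$age_my, 6.6)
  expect_true(young$monophyletic)
  old <- assign_age(mk(species_age_table()$species))
  expect_equal(old$defining_species, "bushbaby")
  expect_equal(old$age_my, 63.7)
  # presence gap: human + gibbon without chimp/gorilla/orangutan
  expect_warning(gap <- assign_age(mk(c("human", "gibbon"))), "presence gap")
  expect_equal(gap$age_my, species_age_table()$age_my[5])
  expect_false(gap$monophyletic)
  expect_error(
    suppressWarnings(assign_age(mk("chimp"))),
    "absent from human"
  )
})

test_that("assign_age equals brute-force max over present species on random rows", {
  set.seed(52)
  ages <- species_age_table()
  for (rep in 1:25) {
    present <- c(TRUE, runif(11) < 0.5) # human always present
    row <- tibble::tibble(locus = "l", species = ages$species, present = present)
    got <- suppressWarnings(assign_age(row))
    expect_equal(got$age_my, max(ages$age_my[present]))
  }
})

test_that("clean-mode simulation ages are recovered exactly", {
  pm <- simulate_presence_matrix(seed = 53)
  ages <- assign_age(pm)
  truth <- attr(pm, "truth")
  joined <- dplyr::inner_join(ages, truth, by = "locus")
  expect_equal(joined$age_my.x, joined$age_my.y)
  expect_true(all(joined$monophyletic))
})

test_that("the exact rank-sum test matches complete enumeration", {
  got <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 2 / 6)
  expect_equal(got$method, "exact")
  set.seed(54)
  for (rep in 1:10) {
    x <- sample(1000, sample(3:6, 1))
    y <- sample(2000:3000, sample(3:6, 1))
    got <- rank_sum_test(x, y)
    expect_equal(got$p_value, oracle_mw_exact(x, y), tolerance = 1e-12)
  }
})

test_that("identical samples are far from significant", {
  x <- c(3, 1, 4, 1, 5)
  expect_gt(rank_sum_test(x, x)$p_value, 0.5)
})

test_that("normal approximation agrees with the exact test at n = 8 vs 8", {
  set.seed(55)
  for (rep in 1:10) {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    p_exact <- rank_sum_test(x, y, exact = TRUE)$p_value
    p_approx <- rank_sum_test(x, y, exact = FALSE)$p_value
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("tied data fall back to the corrected normal approximation", {
  got <- rank_sum_test(c(1, 1, 2, 3), c(2, 3, 3, 4))
  expect_equal(got$method, "normal approximation")
  expect_true(got$p_value > 0 && got$p_value <= 1)
})

test_that("category contrasts separate young from old and skip empty groups", {
  ages <- tibble::tibble(
    locus = sprintf("l%02d", 1:23),
    category = c(rep("crc_specific", 14), rep("silent", 4), rep("constitutive", 5)),
    age_my = c(runif(14, 5, 9), runif(9, 25, 45))
  )
  out <- compare_category_ages(ages)
  expect_equal(nrow(out), 4)
  crc_rows <- out[startsWith(out$contrast, "crc"), ]
  expect_true(all(crc_rows$p_value < 0.01))
  expect_message(
    out3 <- compare_category_ages(ages[ages$category != "silent", ]),
    "skipping"
  )
  expect_equal(nrow(out3), 2) # crc-vs-silent dropped; pooled contrast keeps constitutive
})

test_that("species ages can be read from an ultrametric Newick tree", {
  nw <- "((human:6.6,chimp:6.6):10,gorilla:16.6);"
  tf <- withr::local_tempfile(fileext = ".nwk")
  writeLines(nw, tf)
  ages <- species_ages_from_tree(tf)
  expect_equal(ages$age_my[ages$species == "human"], 0)
  expect_equal(ages$age_my[ages$species == "chimp"], 6.6)
  expect_equal(ages$age_my[ages$species == "gorilla"], 16.6)
})
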