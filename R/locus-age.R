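#' Presence calls from per-species alignment coverage
#'
#' A locus is considered present in a species when the fraction of its
#' human sequence covered by the species' alignment reaches
#' `min_coverage`; the boundary case (coverage exactly at the threshold)
#' counts as present.
#'
#' @param coverage tibble with columns `locus`, `species`, `coverage`
#'   (fractions in `[0, 1]`).
#' @param min_coverage presence threshold (default 0.5; the published
#'   extraction pipelines leave the exact criterion open, so this is a
#'   documented convention).
#' @return `coverage` with a logical `present` column.
#' @export
presence_from_coverage <- function(coverage, min_coverage = 0.5) {
  assert_columns(coverage, c("locus", "species", "coverage"), "coverage")
  assert_probability(coverage$coverage, "coverage")
  assert_probability(min_coverage, "min_coverage")
  coverage |> mutate(present = .data$coverage >= min_coverage)
}

#' Flanking-sequence orthology check
#'
#' Verifies that a putative ortholog sits in the same genomic context by
#' comparing the sequence directly flanking the locus in human with the
#' corresponding species flank: ungapped identity over the first
#' `flank_len` aligned positions must reach `min_identity`. Positions where
#' either sequence carries a gap (`-`) or `N` are excluded from both
#' numerator and denominator.
#'
#' @param human_flank,species_flank character strings over A/C/G/T/N/-
#'   (case-insensitive), aligned, each at least `flank_len` long.
#' @param min_identity identity fraction required (default 0.7).
#' @param flank_len number of aligned positions compared (default 500).
#' @return Logical: orthologous or not, with attributes `identity` and
#'   `n_compared`.
#' @export
flank_orthology_check <- function(human_flank, species_flank,
                                  min_identity = 0.7, flank_len = 500) {
  if (!nzchar(human_flank %||% "") || !nzchar(species_flank %||% "")) {
    abort("empty flanking sequence")
  }
  assert_probability(min_identity, "min_identity")
  a <- strsplit(toupper(human_flank), "")[[1]]
  b <- strsplit(toupper(species_flank), "")[[1]]
  if (length(a) < flank_len || length(b) < flank_len) {
    abort(sprintf("flanking sequences must span at least %d positions", flank_len))
  }
  a <- a[seq_len(flank_len)]
  b <- b[seq_len(flank_len)]
  ok <- !(a %in% c("-", "N")) & !(b %in% c("-", "N"))
  if (!any(ok)) abort("no comparable (gap-free, non-N) positions in the flanks")
  identity <- mean(a[ok] == b[ok])
  structure(identity >= min_identity, identity = identity, n_compared = sum(ok))
}

#' Insertion age of loci from primate presence/absence
#'
#' Each locus is dated by the split age between human and the most distant
#' species in which the locus is found: the locus must already have been in
#' the genome of their common ancestor. Rows whose presence pattern is not
#' phylogenetically consistent (a species closer than the defining species
#' lacks the locus — possible lineage-specific deletion or alignment gap)
#' are still dated by the same most-distant rule but flagged with a
#' presence-gap warning and `monophyletic = FALSE`.
#'
#' @param presence tibble with columns `locus`, `species`, `present`
#'   (optionally `category`, which is carried through).
#' @param species_ages tibble as [species_age_table()]; ages in My,
#'   non-decreasing with divergence order, human = 0.
#' @return A tibble `locus` (, `category`), `defining_species`, `age_my`,
#'   `monophyletic`.
#' @export
assign_age <- function(presence, species_ages = species_age_table()) {
  assert_columns(presence, c("locus", "species", "present"), "presence")
  assert_columns(species_ages, c("species", "age_my"), "species_ages")
  if (is.unsorted(species_ages$age_my)) {
    abort("`species_ages` must be ordered by divergence (non-decreasing ages)")
  }
  unknown <- setdiff(unique(presence$species), species_ages$species)
  if (length(unknown) > 0L) {
    abort(sprintf("species without a split age: %s", paste(unknown, collapse = ", ")))
  }
  has_category <- "category" %in% names(presence)
  out <- presence |>
    left_join(species_ages, by = "species") |>
    group_by(.data$locus) |>
    group_map(function(d, key) {
      human_row <- d$species == "human"
      if (!any(human_row & d$present)) {
        abort(sprintf("locus %s absent from human; cannot assign an age", key$locus))
      }
      pres <- d[d$present, ]
      i <- which.max(pres$age_my)
      age <- pres$age_my[i]
      # consistent iff every species at or below the defining age is present
      mono <- all(d$present[d$age_my <= age])
      tibble(
        locus = key$locus,
        category = if (has_category) d$category[1] else NA_character_,
        defining_species = pres$species[i],
        age_my = age, monophyletic = mono
      )
    }) |>
    list_rbind()
  if (!has_category) out$category <- NULL
  gaps <- out$locus[!out$monophyletic]
  if (length(gaps) > 0L) {
    warn(sprintf(
      "presence gap (non-monophyletic pattern) for locus/loci: %s",
      paste(gaps, collapse = ", ")
    ))
  }
  out
}

#' Two-sample Mann-Whitney/Wilcoxon rank-sum test
#'
#' Exact enumeration of the null distribution of U when both groups have at
#' most 8 observations and the data are tie-free; otherwise the normal
#' approximation with tie and continuity correction. Wraps
#' [stats::wilcox.test()].
#'
#' @param x,y numeric vectors; both non-empty, combined length at least 4.
#' @param exact override the automatic exact/approximate choice.
#' @return A tibble `statistic` (the Mann-Whitney U for `x`), `p_value`,
#'   `method`.
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  if (length(x) == 0L || length(y) == 0L) abort("both groups must be non-empty")
  if (length(x) + length(y) < 4L) abort("need at least 4 observations in total")
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- length(x) <= 8L && length(y) <= 8L && !ties
  if (length(unique(c(x, y))) == 1L) {
    # fully tied data carry no ordering information at all
    return(tibble(
      statistic = length(x) * length(y) / 2, p_value = 1,
      method = "normal approximation"
    ))
  }
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact && !ties, correct = TRUE)
  )
  tibble(
    statistic = unname(ht$statistic), p_value = ht$p.value,
    method = if (exact && !ties) "exact" else "normal approximation"
  )
}

#' Rank-sum contrasts of insertion ages between locus categories
#'
#' Computes the four category contrasts of interest: CRC-specific vs
#' silent, CRC-specific vs constitutive, CRC-specific vs silent +
#' constitutive pooled, and silent vs constitutive. Contrasts with an empty
#' side are skipped with a message.
#'
#' @param ages tibble with columns `locus`, `category`, `age_my` (as from
#'   [assign_age()] on categorized presence data).
#' @return A tibble `contrast`, `n1`, `n2`, `median1`, `median2`,
#'   `statistic`, `p_value`, `stars`.
#' @export
compare_category_ages <- function(ages) {
  assert_columns(ages, c("locus", "category", "age_my"), "ages")
  pull_ages <- function(cats) ages$age_my[ages$category %in% cats]
  contrasts <- list(
    crc_vs_silent = list(a = "crc_specific", b = "silent"),
    crc_vs_constitutive = list(a = "crc_specific", b = "constitutive"),
    crc_vs_silent_constitutive = list(a = "crc_specific", b = c("silent", "constitutive")),
    silent_vs_constitutive = list(a = "silent", b = "constitutive")
  )
  purrr::imap(contrasts, function(ct, nm) {
    x <- pull_ages(ct$a)
    y <- pull_ages(ct$b)
    if (length(x) == 0L || length(y) == 0L) {
      inform(sprintf("skipping contrast %s: empty category", nm))
      return(NULL)
    }
    rs <- rank_sum_test(x, y)
    tibble(
      contrast = nm, n1 = length(x), n2 = length(y),
      median1 = median(x), median2 = median(y),
      statistic = rs$statistic, p_value = rs$p_value
    )
  }) |>
    list_rbind() |>
    mutate(stars = p_stars(.data$p_value))
}

#' Species split ages from an ultrametric Newick tree
#'
#' Convenience reader for node ages supplied as a dated (ultrametric,
#' My-scaled branch lengths) species tree instead of a table: the split age
#' of each species is half its patristic distance to `human`. Requires the
#' `ape` package.
#'
#' @param path path to a Newick file.
#' @param reference name of the reference tip (default `"human"`).
#' @return A tibble `species`, `age_my`, ordered by increasing age.
#' @export
species_ages_from_tree <- function(path, reference = "human") {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("reading Newick trees requires the 'ape' package")
  }
  tree <- ape::read.tree(path)
  if (!reference %in% tree$tip.label) {
    abort(sprintf("tip '%s' not found in the tree", reference))
  }
  d <- ape::cophenetic.phylo(tree)[reference, ]
  tibble(species = names(d), age_my = unname(d) / 2) |>
    arrange(.data$age_my)
}

#' Read a species split-age table
#'
#' @param path TSV with columns `species`, `age_my`.
#' @return A tibble ordered by increasing age.
#' @export
read_species_ages <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(out, c("species", "age_my"), "species ages file")
  out |> arrange(.data$age_my)
}
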