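#' Primate species panel with human-split ages
#'
#' Twelve primates ordered by divergence from human, with the approximate
#' age (million years, My) of the human lineage split for each. The ages are
#' round-figure transcriptions of published primate divergence-time
#' estimates (apes a few to ~20 My, Old World monkeys ~29 My, New World
#' monkeys ~41 My, strepsirrhines ~64 My); they are external constants of
#' the analysis, supplied here as a convenience default and replaceable via
#' [read_species_ages()]. Species of the same clade share a split age, so
#' ages are non-decreasing (not strictly increasing) along the panel.
#'
#' @return A tibble with columns `species` and `age_my`, ordered by
#'   increasing divergence from human.
#' @export
species_age_table <- function() {
  tibble(
    species = c(
      "human", "chimp", "gorilla", "orangutan", "gibbon",
      "rhesus_macaque", "crab_eating_macaque", "hamadryas_baboon",
      "vervet_monkey", "marmoset", "squirrel_monkey", "bushbaby"
    ),
    age_my = c(0, 6.6, 8.8, 16.8, 19.2, 29.2, 29.2, 29.2, 29.2, 40.6, 40.6, 63.7)
  )
}

#' Default locus category set
#'
#' 14 CRC-specific loci, 5 constitutively expressed, 4 silent and 2
#' gonads-restricted loci — the category sizes used throughout the
#' evolutionary analyses.
#'
#' @return A tibble with columns `locus` and `category`.
#' @export
default_loci <- function() {
  tibble(
    locus = c(
      sprintf("crc_%02d", 1:14), sprintf("const_%02d", 1:5),
      sprintf("silent_%02d", 1:4), sprintf("gonad_%02d", 1:2)
    ),
    category = c(
      rep("crc_specific", 14), rep("constitutive", 5),
      rep("silent", 4), rep("gonads", 2)
    )
  )
}

#' Default insertion-node distributions per locus category
#'
#' CRC-specific loci are drawn from young insertion nodes (shared only with
#' chimp or gorilla), silent and constitutive loci from old nodes (gibbon
#' and beyond), gonads-restricted loci in between — emulating the finding
#' that tumor-reactivated proviruses belong to evolutionarily young
#' subfamilies.
#'
#' @return A named list mapping category to a named probability vector over
#'   defining (most distant sharing) species.
#' @export
default_insertion_probs <- function() {
  list(
    crc_specific = c(chimp = 0.5, gorilla = 0.5),
    gonads = c(orangutan = 0.5, gibbon = 0.5),
    silent = c(
      gibbon = 0.2, rhesus_macaque = 0.3, vervet_monkey = 0.2,
      marmoset = 0.2, bushbaby = 0.1
    ),
    constitutive = c(
      rhesus_macaque = 0.3, hamadryas_baboon = 0.2, marmoset = 0.3,
      squirrel_monkey = 0.1, bushbaby = 0.1
    )
  )
}

#' Simulate a loci-by-species presence/absence matrix
#'
#' For each locus an insertion node (its most distant sharing species) is
#' sampled from the category's node distribution; the locus is then present
#' in every species whose human-split age does not exceed that node's age.
#' In this clean mode presence is phylogenetically consistent by
#' construction (no gain after loss along the divergence ordering, human
#' always present). A noisy mode flips non-human presences to absent with
#' probability `noise_rate`, emulating orthology-check failures.
#'
#' @param loci tibble with columns `locus`, `category`.
#' @param species_ages tibble as [species_age_table()].
#' @param node_probs named list as [default_insertion_probs()]; every
#'   category in `loci` must appear.
#' @param noise_rate probability of dropping a (non-human) presence.
#' @param seed optional integer seed.
#' @return A tibble with columns `locus`, `category`, `species`, `present`,
#'   with the sampled truth in attribute `truth` (tibble: `locus`,
#'   `defining_species`, `age_my`).
#' @export
simulate_presence_matrix <- function(loci = default_loci(),
                                     species_ages = species_age_table(),
                                     node_probs = default_insertion_probs(),
                                     noise_rate = 0, seed = NULL) {
  assert_columns(loci, c("locus", "category"), "loci")
  assert_columns(species_ages, c("species", "age_my"), "species_ages")
  assert_probability(noise_rate, "noise_rate")
  unknown <- setdiff(unique(loci$category), names(node_probs))
  if (length(unknown) > 0L) {
    abort(sprintf("no insertion-node distribution for category: %s",
                  paste(unknown, collapse = ", ")))
  }
  bad_sp <- setdiff(unlist(lapply(node_probs, names)), species_ages$species)
  if (length(bad_sp) > 0L) {
    abort(sprintf("unknown species in `node_probs`: %s", paste(bad_sp, collapse = ", ")))
  }
  with_seed(seed, {
    defining <- purrr::map_chr(loci$category, function(cat) {
      p <- node_probs[[cat]]
      sample(names(p), 1L, prob = p)
    })
    ages <- setNames(species_ages$age_my, species_ages$species)
    truth <- tibble(
      locus = loci$locus, defining_species = defining,
      age_my = unname(ages[defining])
    )
    out <- tidyr::crossing(loci, species_ages) |>
      left_join(
        truth |> rename(insertion_age = "age_my"),
        by = "locus"
      ) |>
      mutate(present = .data$age_my <= .data$insertion_age) |>
      arrange(
        match(.data$locus, loci$locus),
        match(.data$species, species_ages$species)
      ) |>
      select("locus", "category", "species", "present")
    if (noise_rate > 0) {
      flip <- runif(nrow(out)) < noise_rate & out$species != "human"
      out$present <- out$present & !flip
    }
    attr(out, "truth") <- truth
    out
  })
}
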