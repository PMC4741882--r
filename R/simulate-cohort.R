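#' Default qRT-PCR assay systems
#'
#' The twelve assay systems of the default study design: five HERV-H target
#' loci (named by chromosome-of-origin locus identifiers), a colon-tissue
#' positive and a negative HERV-H control, two conventional tumor markers
#' (MMP7, OPN), and three housekeeping genes (G6PD, GAPDH, HPRT) used for
#' geometric-mean normalization.
#'
#' @return A tibble with columns `system` and
#'   `role` (one of `target`, `herv_pos_control`, `herv_neg_control`,
#'   `tumor_marker`, `housekeeping`).
#' @export
default_systems <- function() {
  tibble(
    system = c(
      "X00041_h_gag", "2000045_h", "500502_h", "1400035_h", "1300360_h_gag",
      "1900007_h_L3U3", "1900006_h_env", "MMP7", "OPN",
      "G6PD", "GAPDH", "HPRT"
    ),
    role = c(
      rep("target", 5),
      "herv_pos_control", "herv_neg_control",
      rep("tumor_marker", 2),
      rep("housekeeping", 3)
    )
  )
}

#' Default per-system positivity model
#'
#' Tumor positivity probabilities follow the ordering reported for CRC
#' cohorts (the X-linked locus expressed in about half of tumors down to 17%
#' for the least frequent locus); normal tissue is almost never positive.
#' Microsatellite-instability and lymph-node effects enter as odds ratios on
#' the tumor probability: the loci most representative of the MSI
#' association (chromosomes X, 20 and 14) carry a strong MSI odds ratio, the
#' chromosome 5 locus trends the opposite way, and the chromosome 5 and 20
#' loci carry a nodal-invasion odds ratio. Magnitudes of the odds ratios are
#' simulation conventions, not estimates.
#'
#' @return A tibble with columns `system`, `p_tumor`, `p_normal`,
#'   `p_adenoma`, `p_metastasis`, `msi_or`, `n_or`. Housekeeping systems are
#'   absent: they are always expressed.
#' @export
default_positivity <- function() {
  tribble(
    ~system,          ~p_tumor, ~p_normal, ~p_adenoma, ~p_metastasis, ~msi_or, ~n_or,
    "X00041_h_gag",   0.50,     0,         0.29,       0.50,          8,       1,
    "2000045_h",      0.33,     0,         0.33,       0.10,          8,       4,
    "500502_h",       0.27,     0,         0.24,       0.10,          0.6,     4,
    "1400035_h",      0.22,     0,         0.10,       0.10,          8,       1,
    "1300360_h_gag",  0.17,     0,         0.05,       0.69,          1,       1,
    "1900007_h_L3U3", 0.63,     0.62,      0.60,       0.80,          1,       1,
    "1900006_h_env",  0.005,    0.005,     0.005,      0.005,         1,       1,
    "MMP7",           0.63,     0.04,      0.30,       0.50,          1,       1,
    "OPN",            0.79,     0.01,      0.50,       0.60,          1,       1
  )
}

#' Configure a synthetic qRT-PCR cohort
#'
#' Bundles everything the cohort generator needs: paired tumor/normal sample
#' sizes per named cohort, the assay systems and their roles, the stratified
#' positivity model, cohort-specific Ct ceilings used to censor undetected
#' reactions, and the Ct distributions of expressed reactions and
#' housekeeping genes.
#'
#' @param n_pairs named integer vector: number of tumor/normal pairs per
#'   cohort. Defaults to 70 + 69 = 139 pairs across two biobank cohorts.
#' @param systems tibble as [default_systems()].
#' @param positivity tibble as [default_positivity()].
#' @param ct_ceiling named numeric vector, cycles: Ct values above the
#'   ceiling of the sample's cohort are censored at the ceiling (33 for the
#'   first default cohort, 32 for the other).
#' @param expressed_ct_range length-2 numeric, cycles: expressed reactions
#'   draw Ct uniformly from this interval.
#' @param hk_ct_mean_sd length-2 numeric: mean and SD (cycles) of the normal
#'   distribution housekeeping Ct values are drawn from.
#' @param msi_prob probability that a tumor is MSI (default 0.22, i.e. 25 of
#'   116 genotyped tumors).
#' @param n_status_probs named probabilities for tumor N status, summing
#'   to 1.
#' @param n_adenoma,n_metastasis numbers of unpaired adenoma / liver
#'   metastasis samples appended to the first cohort.
#' @return An object of class `herv_cohort_config` (a list).
#' @export
cohort_config <- function(n_pairs = c(rostock = 70, reims = 69),
                          systems = default_systems(),
                          positivity = default_positivity(),
                          ct_ceiling = c(rostock = 33, reims = 32),
                          expressed_ct_range = c(22, 30),
                          hk_ct_mean_sd = c(20, 1),
                          msi_prob = 0.22,
                          n_status_probs = c(N0 = 0.45, N1 = 0.35, N2 = 0.20),
                          n_adenoma = 0,
                          n_metastasis = 0) {
  if (is.null(names(n_pairs)) || any(names(n_pairs) == "")) {
    abort("`n_pairs` must be a named vector (one entry per cohort)")
  }
  if (any(n_pairs < 0) || any(n_pairs != floor(n_pairs))) {
    abort("`n_pairs` entries must be non-negative integers")
  }
  if (n_adenoma < 0 || n_metastasis < 0) abort("sample counts must be non-negative")
  assert_columns(systems, c("system", "role"), "systems")
  assert_columns(
    positivity,
    c("system", "p_tumor", "p_normal", "msi_or", "n_or"), "positivity"
  )
  if (!"p_adenoma" %in% names(positivity)) positivity$p_adenoma <- positivity$p_tumor
  if (!"p_metastasis" %in% names(positivity)) positivity$p_metastasis <- positivity$p_tumor
  assert_probability(
    unlist(positivity[c("p_tumor", "p_normal", "p_adenoma", "p_metastasis")]),
    "positivity"
  )
  assert_probability(msi_prob, "msi_prob")
  assert_probability(n_status_probs, "n_status_probs")
  if (abs(sum(n_status_probs) - 1) > 1e-8) abort("`n_status_probs` must sum to 1")
  if (any(positivity$msi_or <= 0) || any(positivity$n_or <= 0)) {
    abort("odds ratios must be positive")
  }
  missing_ceiling <- setdiff(names(n_pairs), names(ct_ceiling))
  if (length(missing_ceiling) > 0L) {
    abort(sprintf("no Ct ceiling for cohort(s): %s", paste(missing_ceiling, collapse = ", ")))
  }
  in_cycles <- function(x) all(is.finite(x) & x > 0 & x < 45)
  if (!in_cycles(ct_ceiling) || !in_cycles(expressed_ct_range) || !in_cycles(hk_ct_mean_sd[1])) {
    abort("Ct ceilings and ranges must lie within (0, 45) cycles")
  }
  if (diff(expressed_ct_range) < 0) abort("`expressed_ct_range` must be increasing")
  non_hk <- systems$system[systems$role != "housekeeping"]
  if (!all(non_hk %in% positivity$system)) {
    abort("every non-housekeeping system needs a row in `positivity`")
  }
  structure(
    list(
      n_pairs = n_pairs, systems = systems, positivity = positivity,
      ct_ceiling = ct_ceiling, expressed_ct_range = expressed_ct_range,
      hk_ct_mean_sd = hk_ct_mean_sd, msi_prob = msi_prob,
      n_status_probs = n_status_probs,
      n_adenoma = n_adenoma, n_metastasis = n_metastasis
    ),
    class = "herv_cohort_config"
  )
}

# Solve the baseline logit so that the MSI/N-stratified tumor probabilities
# mix back to the configured marginal tumor positivity.
solve_base_logit <- function(p_marginal, msi_or, n_or, w_msi, w_nplus) {
  if (p_marginal <= 0) return(-Inf)
  if (p_marginal >= 1) return(Inf)
  weights <- c(
    (1 - w_msi) * (1 - w_nplus), (1 - w_msi) * w_nplus,
    w_msi * (1 - w_nplus), w_msi * w_nplus
  )
  shifts <- c(0, log(n_or), log(msi_or), log(msi_or) + log(n_or))
  f <- function(l) sum(weights * stats::plogis(l + shifts)) - p_marginal
  stats::uniroot(f, c(-30, 30), tol = 1e-12)$root
}

#' Generate a synthetic paired tumor/normal qRT-PCR cohort
#'
#' Produces a long Ct table (one row per reaction), a clinical annotation
#' table, and a ground-truth record of every reaction's expressed/censored
#' state and sampling probability. Expressed reactions draw Ct uniformly
#' from the configured range; non-expressed reactions are censored exactly
#' at their cohort's Ct ceiling; housekeeping genes are always expressed
#' with normally distributed Ct.
#'
#' @param config a [cohort_config()] object.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return A list of class `herv_cohort` with elements `ct` (tibble:
#'   `sample`, `system`, `ct`, `censored`), `annotations` (tibble: `sample`,
#'   `patient`, `tissue_class`, `organ`, `cohort`, `msi_status`,
#'   `n_status`), and `truth` (list with per-reaction tibble `reactions`
#'   and the config).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "herv_cohort_config"))
  with_seed(seed, {
    ann <- build_annotations(config)
    ct <- simulate_ct_layer(config, ann)
    structure(
      list(
        ct = ct$ct,
        annotations = ann,
        truth = list(reactions = ct$truth, config = config)
      ),
      class = "herv_cohort"
    )
  })
}

build_annotations <- function(config) {
  cohorts <- names(config$n_pairs)
  paired <- purrr::imap(config$n_pairs, function(n, cohort) {
    if (n == 0L) return(NULL)
    patient <- sprintf("%s_p%03d", cohort, seq_len(n))
    tibble(
      sample = c(paste0(patient, "_T"), paste0(patient, "_N")),
      patient = rep(patient, 2),
      tissue_class = rep(c("tumor", "normal"), each = n),
      organ = "colon",
      cohort = cohort,
      msi_status = c(
        sample(c("MSI", "MSS"), n, TRUE, c(config$msi_prob, 1 - config$msi_prob)),
        rep("unknown", n)
      ),
      n_status = c(
        sample(names(config$n_status_probs), n, TRUE, config$n_status_probs),
        rep("unknown", n)
      )
    )
  }) |> list_rbind()
  extra <- function(n, class, organ, prefix) {
    if (n == 0L) return(NULL)
    patient <- sprintf("%s_%s%03d", cohorts[1], prefix, seq_len(n))
    tibble(
      sample = paste0(patient, "_", toupper(substr(class, 1, 1))),
      patient = patient, tissue_class = class, organ = organ,
      cohort = cohorts[1], msi_status = "unknown", n_status = "unknown"
    )
  }
  bind_rows(
    paired,
    extra(config$n_adenoma, "adenoma", "colon", "a"),
    extra(config$n_metastasis, "metastasis", "liver", "m")
  )
}

simulate_ct_layer <- function(config, ann) {
  w_nplus <- 1 - unname(config$n_status_probs["N0"])
  pos <- config$positivity |>
    mutate(base_logit = purrr::pmap_dbl(
      list(.data$p_tumor, .data$msi_or, .data$n_or),
      solve_base_logit,
      w_msi = config$msi_prob, w_nplus = w_nplus
    ))

  grid <- tidyr::crossing(ann, config$systems) |>
    left_join(pos, by = "system") |>
    mutate(
      p_expressed = dplyr::case_when(
        role == "housekeeping" ~ 1,
        tissue_class == "normal" ~ .data$p_normal,
        tissue_class == "adenoma" ~ .data$p_adenoma,
        tissue_class == "metastasis" ~ .data$p_metastasis,
        tissue_class == "tumor" ~ stats::plogis(
          .data$base_logit +
            log(.data$msi_or) * (.data$msi_status == "MSI") +
            log(.data$n_or) * (.data$n_status %in% c("N1", "N2"))
        )
      ),
      expressed = runif(dplyr::n()) < .data$p_expressed,
      ceiling = unname(config$ct_ceiling[.data$cohort]),
      ct = dplyr::case_when(
        role == "housekeeping" ~ pmin(
          pmax(rnorm(dplyr::n(), config$hk_ct_mean_sd[1], config$hk_ct_mean_sd[2]), 5),
          .data$ceiling
        ),
        expressed ~ runif(
          dplyr::n(), config$expressed_ct_range[1], config$expressed_ct_range[2]
        ),
        TRUE ~ .data$ceiling
      ),
      censored = !.data$expressed & .data$role != "housekeeping"
    )
  list(
    ct = grid |> select("sample", "system", "ct", "censored"),
    truth = grid |>
      select(
        "sample", "system", "role", "tissue_class", "msi_status", "n_status",
        "p_expressed", "expressed", "censored"
      )
  )
}

#' @export
print.herv_cohort <- function(x, ...) {
  cat(
    "<herv_cohort>", nrow(x$annotations), "samples x",
    length(unique(x$ct$system)), "assay systems;",
    sum(x$truth$reactions$expressed), "of", nrow(x$ct), "reactions expressed\n"
  )
  invisible(x)
}
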