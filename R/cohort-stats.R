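#' Two-sample t-test (Welch by default)
#'
#' Thin, contract-checked wrapper around [stats::t.test()] returning a tidy
#' one-row tibble. Welch-Satterthwaite degrees of freedom by default;
#' `var_equal = TRUE` gives the pooled Student variant.
#'
#' @param x,y numeric vectors, each of length at least 2, finite.
#' @param var_equal pool the variances?
#' @return A tibble with `statistic`, `df`, `p_value`, `method`.
#' @export
welch_t_test <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2L || length(y) < 2L) abort("each group needs at least 2 values")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("values must be finite")
  if (sd(x) == 0 && sd(y) == 0) {
    # degenerate constant groups: no variance to test against
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble(
      statistic = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
      df = NA_real_,
      p_value = if (same) 1 else .Machine$double.xmin,
      method = "degenerate (zero variance)"
    ))
  }
  ht <- t.test(x, y, var.equal = var_equal)
  tibble(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, method = ht$method
  )
}

#' Group comparisons of expression per assay system
#'
#' Runs, per system, the group contrast implied by `factor`:
#' * `tissue`: tumor vs adjacent normal;
#' * `msi`: MSI vs MSS tumors;
#' * `n_status`: lymph-node-positive (N1 or N2) vs N0 tumors (the headline
#'   dichotomy; a descriptive three-group mean table is attached as
#'   attribute `n_status_means`).
#'
#' Values are transformed with `log2(1 + x)` by default: scaled relative
#' expression spans orders of magnitude with a point mass at the censoring
#' floor, and on the raw scale the t-test's type-I error is inflated well
#' above nominal at these group sizes. Use `transform = "identity"` for
#' raw-scale tests. Comparisons whose factor levels are missing are skipped
#' with a message. No multiple-testing correction is applied by default;
#' `adjust = "BH"` adds a Benjamini-Hochberg column.
#'
#' @param expr expression table with `sample`, `system`, `scaled_re`.
#' @param annotations clinical annotation tibble (see [simulate_cohort()]).
#' @param factor one of `"tissue"`, `"msi"`, `"n_status"`.
#' @param systems optional character vector restricting the systems tested.
#' @param transform `"log2"` (default) or `"identity"`.
#' @param var_equal,paired test variant flags; `paired` (tissue factor
#'   only) pairs tumor and normal through the `patient` column.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble of class `herv_comparisons`: `system`, `factor`,
#'   `group1`, `group2`, `n1`, `n2`, `mean1`, `mean2`, `statistic`, `df`,
#'   `p_value`, `stars` (and `p_adj` if requested). Means are on the
#'   transformed scale.
#' @export
compare_groups <- function(expr, annotations,
                           factor = c("tissue", "msi", "n_status"),
                           systems = NULL,
                           transform = c("log2", "identity"),
                           var_equal = FALSE, paired = FALSE,
                           adjust = c("none", "BH")) {
  factor <- arg_match(factor)
  transform <- arg_match(transform)
  adjust <- arg_match(adjust)
  assert_columns(expr, c("sample", "system", "scaled_re"), "expr")
  tf <- if (transform == "log2") function(x) log2(1 + x) else identity
  dat <- expr |>
    inner_join(annotations, by = "sample") |>
    mutate(value = tf(.data$scaled_re))
  if (!is.null(systems)) dat <- dat |> filter(.data$system %in% systems)

  spec <- switch(factor,
    tissue = list(
      data = dat |> filter(.data$tissue_class %in% c("tumor", "normal")),
      group = "tissue_class", g1 = "tumor", g2 = "normal"
    ),
    msi = list(
      data = dat |> filter(.data$tissue_class == "tumor", .data$msi_status %in% c("MSI", "MSS")),
      group = "msi_status", g1 = "MSI", g2 = "MSS"
    ),
    n_status = list(
      data = dat |>
        filter(.data$tissue_class == "tumor", .data$n_status %in% c("N0", "N1", "N2")) |>
        mutate(n_group = ifelse(.data$n_status == "N0", "N0", "N1+N2")),
      group = "n_group", g1 = "N1+N2", g2 = "N0"
    )
  )

  rows <- spec$data |>
    group_by(.data$system) |>
    group_map(function(d, key) {
      x <- d$value[d[[spec$group]] == spec$g1]
      y <- d$value[d[[spec$group]] == spec$g2]
      if (paired && factor == "tissue") {
        wide <- d |>
          select("patient", "tissue_class", "value") |>
          tidyr::pivot_wider(names_from = "tissue_class", values_from = "value",
                             values_fn = mean) |>
          tidyr::drop_na()
        x <- wide$tumor
        y <- wide$normal
      }
      if (length(x) < 2L || length(y) < 2L) {
        inform(sprintf(
          "skipping %s for %s: fewer than 2 samples in a group",
          factor, key$system
        ))
        return(NULL)
      }
      ht <- if (paired && factor == "tissue") {
        pt <- t.test(x, y, paired = TRUE)
        tibble(statistic = unname(pt$statistic), df = unname(pt$parameter),
               p_value = pt$p.value, method = pt$method)
      } else {
        welch_t_test(x, y, var_equal = var_equal)
      }
      tibble(
        system = key$system, factor = factor,
        group1 = spec$g1, group2 = spec$g2,
        n1 = length(x), n2 = length(y),
        mean1 = mean(x), mean2 = mean(y),
        statistic = ht$statistic, df = ht$df, p_value = ht$p_value
      )
    }) |>
    list_rbind()
  if (nrow(rows) > 0L) {
    rows <- rows |> mutate(stars = p_stars(.data$p_value))
    if (adjust == "BH") rows <- rows |> mutate(p_adj = stats::p.adjust(.data$p_value, "BH"))
  }
  if (factor == "n_status" && nrow(spec$data) > 0L) {
    attr(rows, "n_status_means") <- spec$data |>
      group_by(.data$system, .data$n_status) |>
      summarise(n = dplyr::n(), mean_value = mean(.data$value), .groups = "drop")
  }
  class(rows) <- c("herv_comparisons", class(rows))
  rows
}

#' Combined per-sample HERV-H expression value
#'
#' Collapses the target systems to one value per sample, used for the
#' family-level association analyses. The combination rule behind published
#' family-level dot plots is not standardized, so `max` (default), `mean`
#' and `sum` are offered and the rule used is recorded in the `rule`
#' attribute and column.
#'
#' @param expr expression table with `sample`, `system`, `scaled_re`.
#' @param systems character vector of target system names (at least one).
#' @param rule `"max"`, `"mean"` or `"sum"`.
#' @return A tibble `sample`, `combined`, `rule`.
#' @export
combined_herv_value <- function(expr, systems, rule = c("max", "mean", "sum")) {
  rule <- arg_match(rule)
  if (length(systems) == 0L) abort("`systems` must name at least one assay system")
  assert_columns(expr, c("sample", "system", "scaled_re"), "expr")
  fun <- switch(rule, max = max, mean = mean, sum = sum)
  expr |>
    filter(.data$system %in% systems) |>
    group_by(.data$sample) |>
    summarise(combined = fun(.data$scaled_re), .groups = "drop") |>
    mutate(rule = rule)
}
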