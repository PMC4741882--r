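#' Evaluate a diagnostic marker panel
#'
#' A sample is panel-positive when at least one member system is called
#' positive (the any-positive / OR rule). Sensitivity is computed over the
#' `case_class` samples and specificity over the `control_class` samples,
#' with Wilson 95% intervals for both.
#'
#' @param calls output of [call_positivity()].
#' @param annotations tibble mapping `sample` to `tissue_class`.
#' @param members character vector of member system names (at least one,
#'   all present in `calls`).
#' @param case_class,control_class tissue classes forming cases (e.g.
#'   `"tumor"` or `"adenoma"`) and controls (typically adjacent `"normal"`
#'   tissue).
#' @param name optional panel name.
#' @return A one-row tibble of class `herv_panel`: `panel`, `rule`, `tp`,
#'   `fp`, `tn`, `fn`, `sensitivity`, `specificity` and Wilson bounds
#'   `sens_lower`..`spec_upper`; members in attribute `members`.
#' @export
evaluate_panel <- function(calls, annotations, members,
                           case_class = "tumor", control_class = "normal",
                           name = NULL) {
  assert_columns(calls, c("sample", "system", "positive"), "calls")
  assert_columns(annotations, c("sample", "tissue_class"), "annotations")
  if (length(members) == 0L) abort("a panel needs at least one member")
  unknown <- setdiff(members, unique(calls$system))
  if (length(unknown) > 0L) {
    abort(sprintf("panel member(s) not in call matrix: %s", paste(unknown, collapse = ", ")))
  }
  ann <- annotations |> select("sample", "tissue_class")
  status <- calls |>
    filter(.data$system %in% members) |>
    inner_join(ann, by = "sample") |>
    filter(.data$tissue_class %in% c(case_class, control_class)) |>
    group_by(.data$sample, .data$tissue_class) |>
    summarise(panel_positive = any(.data$positive), .groups = "drop")
  cases <- status |> filter(.data$tissue_class == case_class)
  controls <- status |> filter(.data$tissue_class == control_class)
  if (nrow(cases) == 0L) abort(sprintf("no samples of case class '%s'", case_class))
  if (nrow(controls) == 0L) abort(sprintf("no samples of control class '%s'", control_class))
  tp <- sum(cases$panel_positive)
  fn <- nrow(cases) - tp
  fp <- sum(controls$panel_positive)
  tn <- nrow(controls) - fp
  sens <- wilson_ci(tp, tp + fn)
  spec <- wilson_ci(tn, tn + fp)
  out <- tibble(
    panel = name %||% paste(members, collapse = "+"),
    rule = "any_positive",
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens[["estimate"]],
    sens_lower = sens[["lower"]], sens_upper = sens[["upper"]],
    specificity = spec[["estimate"]],
    spec_lower = spec[["lower"]], spec_upper = spec[["upper"]]
  )
  attr(out, "members") <- members
  class(out) <- c("herv_panel", class(out))
  out
}

#' Select the k most expressed target loci as a panel
#'
#' Ranks target systems by positivity frequency among `class_label` samples
#' and returns the top `k` as a panel definition. Ties are broken by higher
#' mean scaled relative expression in the class, then by name; the ranking
#' table (with the tie-break values) is attached as attribute `ranking`.
#'
#' @param calls output of [call_positivity()] (its `scaled_re` column
#'   supplies the tie-break means).
#' @param annotations tibble mapping `sample` to `tissue_class`.
#' @param k panel size.
#' @param class_label tissue class whose frequencies drive the ranking.
#' @param systems optional tibble `system`, `role`: restricts candidates to
#'   `target`-role systems.
#' @return A list of class `panel_definition`: `name`, `members`, `rule`.
#' @export
select_top_expressed <- function(calls, annotations, k, class_label = "tumor",
                                 systems = NULL) {
  assert_columns(calls, c("sample", "system", "positive"), "calls")
  candidates <- if (is.null(systems)) {
    unique(calls$system)
  } else {
    intersect(systems$system[systems$role == "target"], unique(calls$system))
  }
  if (k > length(candidates)) {
    abort(sprintf("k = %d exceeds the %d available systems", k, length(candidates)))
  }
  ann <- annotations |> select("sample", "tissue_class")
  ranking <- calls |>
    filter(.data$system %in% candidates) |>
    inner_join(ann, by = "sample") |>
    filter(.data$tissue_class == class_label) |>
    group_by(.data$system) |>
    summarise(
      frequency = mean(.data$positive),
      mean_scaled_re = if ("scaled_re" %in% names(calls)) mean(.data$scaled_re) else NA_real_,
      .groups = "drop"
    ) |>
    arrange(
      dplyr::desc(.data$frequency), dplyr::desc(.data$mean_scaled_re), .data$system
    )
  members <- ranking$system[seq_len(k)]
  structure(
    list(
      name = sprintf("top%d_%s", k, class_label),
      members = members, rule = "any_positive", ranking = ranking
    ),
    class = "panel_definition"
  )
}

#' @export
print.panel_definition <- function(x, ...) {
  cat("<panel_definition>", x$name, "| rule:", x$rule, "\n  members:",
      paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname evaluate_panel
#' @param x a `herv_panel` object.
#' @param ... unused.
#' @method tidy herv_panel
#' @export
tidy.herv_panel <- function(x, ...) {
  tibble(
    panel = x$panel,
    metric = c("sensitivity", "specificity"),
    estimate = c(x$sensitivity, x$specificity),
    lower = c(x$sens_lower, x$spec_lower),
    upper = c(x$sens_upper, x$spec_upper),
    n = c(x$tp + x$fn, x$tn + x$fp)
  )
}

#' @rdname evaluate_panel
#' @method glance herv_panel
#' @export
glance.herv_panel <- function(x, ...) {
  as_tibble(x)
}
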