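# ggplot2 graphics for the main result types

#' Expression dot plot per assay system
#'
#' Jittered per-sample scaled relative expression on a log10 axis, colored
#' by tissue class — the standard way locus-specific qRT-PCR screens are
#' displayed.
#'
#' @param expr expression table with `sample`, `system`, `scaled_re`.
#' @param annotations tibble mapping `sample` to `tissue_class`.
#' @param systems optional character vector ordering/restricting systems.
#' @return A ggplot object.
#' @export
plot_expression <- function(expr, annotations, systems = NULL) {
  assert_columns(expr, c("sample", "system", "scaled_re"), "expr")
  dat <- expr |> inner_join(annotations |> select("sample", "tissue_class"), by = "sample")
  if (!is.null(systems)) {
    dat <- dat |>
      filter(.data$system %in% systems) |>
      mutate(system = factor(.data$system, levels = systems))
  }
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$system, y = .data$scaled_re, colour = .data$tissue_class
  )) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.6, size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = NULL, y = "scaled relative expression", colour = "tissue"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname compare_groups
#' @param object a `herv_comparisons` tibble.
#' @param ... unused.
#' @method autoplot herv_comparisons
#' @export
autoplot.herv_comparisons <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$system, -log10(.data$p_value)),
    y = -log10(.data$p_value)
  )) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), vjust = -0.3) +
    ggplot2::labs(
      x = NULL, y = expression(-log[10](p)),
      title = paste("group comparison:", object$factor[1])
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Insertion-age distribution per locus category
#'
#' @param ages tibble with `category`, `age_my` (see [assign_age()]).
#' @return A ggplot object.
#' @export
plot_age_distribution <- function(ages) {
  assert_columns(ages, c("category", "age_my"), "ages")
  ggplot2::ggplot(ages, ggplot2::aes(
    x = .data$category, y = .data$age_my, colour = .data$category
  )) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "insertion age (My)") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Heatmap of mean mark-overlap scores
#'
#' @param scores output of [mean_mark_overlap()].
#' @param categories optional tibble `locus`, `category` used to facet rows.
#' @return A ggplot object.
#' @export
plot_overlap_heatmap <- function(scores, categories = NULL) {
  assert_columns(scores, c("locus", "mark", "score"), "scores")
  dat <- as_tibble(scores)
  if (!is.null(categories)) dat <- dat |> inner_join(categories, by = "locus")
  p <- ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$mark, y = .data$locus, fill = .data$score
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "LTR coverage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(categories)) {
    p <- p + ggplot2::facet_grid(rows = ggplot2::vars(.data$category),
                                 scales = "free_y", space = "free_y")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
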