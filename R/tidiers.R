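# broom-style tidiers for the package's result objects

#' @rdname summarize_frequencies
#' @param x a `herv_frequencies` object.
#' @param ... unused.
#' @method tidy herv_frequencies
#' @export
tidy.herv_frequencies <- function(x, ...) {
  x$by_system
}

#' @rdname summarize_frequencies
#' @method glance herv_frequencies
#' @export
glance.herv_frequencies <- function(x, ...) {
  x$per_sample |>
    group_by(.data$tissue_class) |>
    summarise(
      n_samples = dplyr::n(),
      n_any_positive = sum(.data$n_positive_loci > 0),
      mean_positive_loci = mean(.data$n_positive_loci),
      .groups = "drop"
    )
}

#' @rdname compare_groups
#' @param x a `herv_comparisons` tibble.
#' @method tidy herv_comparisons
#' @export
tidy.herv_comparisons <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "herv_comparisons")
  attr(out, "n_status_means") <- NULL
  out
}

#' @rdname mean_mark_overlap
#' @param x a `herv_overlap` tibble.
#' @param ... unused.
#' @method tidy herv_overlap
#' @export
tidy.herv_overlap <- function(x, ...) {
  attr(x, "by_cell_line")
}
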