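#' Per-system positivity thresholds from normal tissue
#'
#' A sample is called expression-positive for an assay system when its
#' scaled relative expression exceeds the mean of the normal-tissue values
#' plus three standard deviations, computed individually for each system.
#' The sample SD (n - 1 denominator) is the default convention; when the
#' normals have zero variance (all at the censoring floor) a tiny epsilon
#' (1e-9) is added so floor-valued samples are not called positive through
#' exact ties.
#'
#' @param expr expression table with a `scaled_re` column (see
#'   [quantify_expression()]).
#' @param annotations tibble mapping `sample` to `tissue_class`.
#' @param normal_class tissue class used as the reference (default
#'   `"normal"`: adjacent normal colon, not adenoma or metastasis tissue).
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @return A tibble with columns `system`, `n_normals`, `mean_normal`,
#'   `sd_normal`, `threshold`.
#' @export
compute_thresholds <- function(expr, annotations, normal_class = "normal",
                               sd_type = c("sample", "population")) {
  sd_type <- arg_match(sd_type)
  assert_columns(expr, c("sample", "system", "scaled_re"), "expr")
  assert_columns(annotations, c("sample", "tissue_class"), "annotations")
  normals <- annotations$sample[annotations$tissue_class == normal_class]
  out <- expr |>
    filter(.data$sample %in% normals) |>
    group_by(.data$system) |>
    summarise(
      n_normals = dplyr::n(),
      mean_normal = mean(.data$scaled_re),
      sd_normal = {
        s <- sd(.data$scaled_re)
        if (sd_type == "population") s * sqrt((dplyr::n() - 1) / dplyr::n()) else s
      },
      .groups = "drop"
    )
  missing <- setdiff(unique(expr$system), out$system)
  too_few <- c(missing, out$system[out$n_normals < 2])
  if (length(too_few) > 0L) {
    abort(sprintf(
      "fewer than 2 %s-tissue samples for system(s): %s",
      normal_class, paste(too_few, collapse = ", ")
    ))
  }
  zero_var <- out$system[out$sd_normal == 0]
  if (length(zero_var) > 0L) {
    inform(sprintf(
      "zero-variance normals for %s: threshold set to mean + 1e-9",
      paste(zero_var, collapse = ", ")
    ))
  }
  out |>
    mutate(threshold = .data$mean_normal + 3 * .data$sd_normal +
             ifelse(.data$sd_normal == 0, 1e-9, 0))
}

#' Binary expression calls against per-system thresholds
#'
#' Strict greater-than comparison of scaled relative expression with the
#' per-system threshold: values exactly at the threshold are negative.
#'
#' @param expr expression table with `sample`, `system`, `scaled_re`.
#' @param thresholds output of [compute_thresholds()].
#' @return A tibble `sample`, `system`, `scaled_re`, `positive`, carrying
#'   `thresholds` in the `thresholds` attribute.
#' @export
call_positivity <- function(expr, thresholds) {
  assert_columns(expr, c("sample", "system", "scaled_re"), "expr")
  assert_columns(thresholds, c("system", "threshold"), "thresholds")
  missing <- setdiff(unique(expr$system), thresholds$system)
  if (length(missing) > 0L) {
    abort(sprintf("no threshold for system(s): %s", paste(missing, collapse = ", ")))
  }
  out <- expr |>
    inner_join(thresholds |> select("system", "threshold"), by = "system") |>
    mutate(positive = .data$scaled_re > .data$threshold) |>
    select("sample", "system", "scaled_re", "positive")
  attr(out, "thresholds") <- thresholds
  out
}

#' Expression-frequency report
#'
#' Summarizes binary calls the way clinical qPCR screens are reported: per
#' tissue class and system the count and fraction of positive samples, per
#' sample the number of positive target loci, and a histogram of samples
#' expressing 0, exactly 1, or 2-5 target loci. When a `systems` role table
#' is supplied, per-sample locus counts are restricted to `target`-role
#' systems (controls and tumor markers still appear in the per-system
#' table).
#'
#' @param calls output of [call_positivity()].
#' @param annotations tibble mapping `sample` to `tissue_class`.
#' @param systems optional tibble with `system`, `role` (see
#'   [default_systems()]).
#' @return An object of class `herv_frequencies`: a list with tibbles
#'   `by_system`, `per_sample` and `histogram`.
#' @export
summarize_frequencies <- function(calls, annotations, systems = NULL) {
  assert_columns(calls, c("sample", "system", "positive"), "calls")
  assert_columns(annotations, c("sample", "tissue_class"), "annotations")
  ann <- annotations |> select("sample", "tissue_class")
  joined <- calls |> inner_join(ann, by = "sample")
  by_system <- joined |>
    group_by(.data$tissue_class, .data$system) |>
    summarise(
      n_pos = sum(.data$positive), n = dplyr::n(),
      frequency = ifelse(dplyr::n() == 0, 0, mean(.data$positive)),
      .groups = "drop"
    )
  target_systems <- if (is.null(systems)) {
    unique(calls$system)
  } else {
    systems$system[systems$role == "target"]
  }
  per_sample <- joined |>
    filter(.data$system %in% target_systems) |>
    group_by(.data$sample, .data$tissue_class) |>
    summarise(n_positive_loci = sum(.data$positive), .groups = "drop")
  histogram <- per_sample |>
    mutate(bin = dplyr::case_when(
      .data$n_positive_loci == 0 ~ "0",
      .data$n_positive_loci == 1 ~ "1",
      .data$n_positive_loci <= 5 ~ "2-5",
      TRUE ~ ">5"
    )) |>
    count(.data$tissue_class, .data$bin, name = "n_samples")
  structure(
    list(by_system = by_system, per_sample = per_sample, histogram = histogram),
    class = "herv_frequencies"
  )
}

#' @export
print.herv_frequencies <- function(x, ...) {
  cat("<herv_frequencies>\n")
  cat("Positive samples per tissue class and system:\n")
  print(x$by_system, n = 30)
  cat("\nSamples by number of positive target loci:\n")
  print(x$histogram)
  invisible(x)
}
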