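#' Second-derivative-maximum Ct of an amplification curve
#'
#' The crossing cycle (Ct) is defined as the position of the maximum of the
#' second derivative of the fluorescence curve, at sub-cycle resolution.
#' The default method fits a four-parameter logistic
#' `B + A / (1 + exp(-(cycle - m)/s))` to all cycles and evaluates the SDM
#' in closed form at `m - s * log(2 + sqrt(3))` (the root of the logistic's
#' third derivative). `method = "discrete"` instead smooths the trace with
#' a short Savitzky-Golay filter, takes central second differences and
#' localizes the maximum by quadratic interpolation; it makes no model
#' assumption but carries a discretization bias of up to ~0.3 cycles and is
#' kept as a fallback for non-sigmoidal traces.
#'
#' Curves with no appreciable amplification (smoothed amplitude below
#' `min_amplitude`) return `NA`, the censored marker; downstream,
#' [apply_ct_ceiling()] turns censored reactions into ceiling-valued Ct.
#'
#' @param curve a tibble with columns `cycle` and `fluorescence` (as from
#'   [simulate_amplification_curve()]), or a bare numeric fluorescence
#'   vector taken to start at cycle 1.
#' @param method `"fit"` (default) or `"discrete"`.
#' @param min_amplitude minimal smoothed peak-to-baseline signal, in
#'   fluorescence units, below which the reaction is called censored.
#' @return Ct in cycles (scalar), or `NA_real_` for a censored reaction.
#' @examples
#' cv <- simulate_amplification_curve("a", "s", target_ct = 23.1, efficiency = 2)
#' sdm_ct(cv)
#' @export
sdm_ct <- function(curve, method = c("fit", "discrete"), min_amplitude = 0.1) {
  method <- arg_match(method)
  f <- curve_fluorescence(curve)
  n <- length(f)
  if (n < 10L) abort("amplification curve too short (need at least 10 cycles)")
  if (any(!is.finite(f))) abort("non-finite fluorescence values")
  smoothed <- signal::sgolayfilt(f, p = 2, n = 5)
  if (max(smoothed) - min(smoothed) < min_amplitude) return(NA_real_)
  if (method == "fit") {
    fit <- fit_logistic(f)
    if (!is.null(fit)) {
      ct <- unname(fit["m"] - fit["s"] * sdm_offset)
      if (is.finite(ct) && ct > 0 && ct < n + 2) return(ct)
    }
    # fall through to the model-free estimate when the fit is unusable
  }
  sdm_discrete(smoothed)
}

# 4-parameter logistic least-squares fit; returns named coefficients or NULL
fit_logistic <- function(f) {
  cyc <- seq_along(f)
  b0 <- min(f)
  a0 <- max(f) - b0
  m0 <- cyc[which.min(abs(f - (b0 + a0 / 2)))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ B + A / (1 + exp(-(cyc - m) / s)),
      start = list(B = b0, A = a0, m = m0, s = 1.5),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  if (!all(is.finite(cf)) || cf[["s"]] <= 0 || cf[["A"]] <= 0) return(NULL)
  cf
}

sdm_discrete <- function(smoothed) {
  d2 <- diff(smoothed, differences = 2)
  i <- which.max(d2)
  ct <- i + 1 # d2[i] approximates the second derivative at cycle i + 1
  if (i > 1L && i < length(d2)) {
    denom <- d2[i - 1] - 2 * d2[i] + d2[i + 1]
    if (denom < 0) ct <- ct + 0.5 * (d2[i - 1] - d2[i + 1]) / denom
  }
  ct
}

curve_fluorescence <- function(curve) {
  if (is.numeric(curve)) return(as.numeric(curve))
  assert_columns(curve, c("cycle", "fluorescence"), "curve")
  curve$fluorescence[order(curve$cycle)]
}

#' Estimate per-cycle amplification efficiency from a curve
#'
#' The default method reuses the logistic fit of [sdm_ct()]: the fitted
#' slope parameter gives `Eff = exp(1 / s)`, the factor by which
#' baseline-subtracted fluorescence multiplies per cycle during the
#' exponential phase. `method = "expfit"` instead regresses
#' `log(fluorescence - baseline)` on cycle over an adaptive exponential
#' -phase window (0.5%-5% of amplitude); it is model-free but usable only
#' on low-noise traces. Estimates are truncated to the plausible range
#' (1, 2.2]; when no estimate can be formed the configured `default` is
#' returned with a warning.
#'
#' @inheritParams sdm_ct
#' @param method `"fit"` (default) or `"expfit"`.
#' @param default efficiency returned when estimation fails (with warning).
#' @return Amplification factor per cycle, in (1, 2.2].
#' @export
estimate_efficiency <- function(curve, method = c("fit", "expfit"),
                                default = 2, min_amplitude = 0.1) {
  method <- arg_match(method)
  f <- curve_fluorescence(curve)
  fallback <- function(reason) {
    warn(sprintf("efficiency estimation failed (%s); using default %.2f", reason, default))
    default
  }
  if (length(f) < 10L || any(!is.finite(f))) return(fallback("unusable curve"))
  smoothed <- signal::sgolayfilt(f, p = 2, n = 5)
  if (max(smoothed) - min(smoothed) < min_amplitude) return(fallback("no amplification"))
  eff <- if (method == "fit") {
    cf <- fit_logistic(f)
    if (is.null(cf)) NA_real_ else exp(1 / cf[["s"]])
  } else {
    b <- min(smoothed)
    a <- max(smoothed) - b
    y <- f - b
    sel <- which(y > 0.005 * a & y < 0.05 * a)
    if (length(sel) < 3L) NA_real_ else {
      exp(unname(coef(lm(log(y[sel]) ~ sel))[2]))
    }
  }
  if (!is.finite(eff) || eff <= 1) return(fallback("estimate out of range"))
  min(eff, 2.2)
}

#' Call Ct and efficiency for a set of amplification curves
#'
#' Convenience wrapper running [sdm_ct()] and [estimate_efficiency()] over
#' a long table of curves, and reducing per-reaction efficiencies to one
#' value per assay system (the median across that system's reactions, a
#' robust choice given occasional poorly fit traces).
#'
#' @param curves tibble with columns `system`, `sample`, `cycle`,
#'   `fluorescence`.
#' @param ... passed on to [sdm_ct()] / [estimate_efficiency()].
#' @return A list with `ct` (tibble `sample`, `system`, `ct`; `NA` =
#'   censored) and `efficiency` (tibble `system`, `eff`, `n_reactions`).
#' @export
ct_from_curves <- function(curves, ...) {
  assert_columns(curves, c("system", "sample", "cycle", "fluorescence"), "curves")
  per_reaction <- curves |>
    group_by(.data$sample, .data$system) |>
    summarise(
      ct = sdm_ct(dplyr::pick("cycle", "fluorescence"), ...),
      eff = if (is.na(ct[1])) NA_real_ else suppressWarnings(
        estimate_efficiency(dplyr::pick("cycle", "fluorescence"))
      ),
      .groups = "drop"
    )
  list(
    ct = per_reaction |> select("sample", "system", "ct"),
    efficiency = per_reaction |>
      group_by(.data$system) |>
      summarise(
        n_reactions = sum(!is.na(.data$eff)),
        eff = if (all(is.na(.data$eff))) 2 else median(.data$eff, na.rm = TRUE),
        .groups = "drop"
      ) |>
      select("system", "eff", "n_reactions")
  )
}

#' Censor Ct values at cohort-specific ceilings
#'
#' Ct values strictly greater than the ceiling of the sample's cohort —
#' and missing Ct from undetected reactions — are set to the ceiling and
#' flagged censored; values at or below the ceiling pass through untouched
#' (a Ct exactly at the ceiling is not censored). Re-applying the ceiling
#' is a no-op. Censoring at a floor value rather than discarding keeps
#' undetected reactions in the expression table as the low end of the
#' dynamic range, avoiding over-interpretation of trace signals.
#'
#' @param ct_tbl tibble with columns `sample`, `system`, `ct` (optionally a
#'   logical `censored` column, which is preserved by OR-ing).
#' @param annotations tibble mapping `sample` to `cohort`.
#' @param ceilings named numeric vector, cycles per cohort.
#' @return `ct_tbl` with `ct` capped and a logical `censored` column.
#' @export
apply_ct_ceiling <- function(ct_tbl, annotations, ceilings) {
  assert_columns(ct_tbl, c("sample", "system", "ct"), "ct_tbl")
  assert_columns(annotations, c("sample", "cohort"), "annotations")
  cohorts <- annotations$cohort[match(ct_tbl$sample, annotations$sample)]
  if (anyNA(cohorts)) abort("some samples are missing from `annotations`")
  unknown <- setdiff(unique(cohorts), names(ceilings))
  if (length(unknown) > 0L) {
    abort(sprintf("no Ct ceiling for cohort(s): %s", paste(unknown, collapse = ", ")))
  }
  ceiling_ct <- unname(ceilings[cohorts])
  previously <- if ("censored" %in% names(ct_tbl)) ct_tbl$censored else FALSE
  ct_tbl |>
    mutate(
      censored = previously | is.na(.data$ct) | .data$ct > ceiling_ct,
      ct = pmin(dplyr::coalesce(.data$ct, ceiling_ct), ceiling_ct)
    )
}

#' Relative expression from Ct values
#'
#' Implements `RE = Eff ^ dCt` with `dCt = Ct_min_series - Ct_sample`,
#' where `Ct_min_series` is the minimum Ct observed for that assay system
#' over the analyzed batch of samples. The sample attaining the series
#' minimum therefore has RE = 1 and every other sample a positive RE below
#' (or equal to) 1; lower Ct means higher expression.
#'
#' @param ct_tbl tibble with `sample`, `system`, `ct` (ceilings already
#'   applied; see [apply_ct_ceiling()]).
#' @param eff either a single amplification factor applied to all systems,
#'   or a tibble with columns `system`, `eff`.
#' @return The input with columns `eff`, `ct_min` and `re` added.
#' @examples
#' ct <- tibble::tibble(
#'   sample = c("a", "b"), system = "sysA",
#'   ct = c(18, 21)
#' )
#' relative_expression(ct, eff = 2)$re # 1 and 0.125
#' @export
relative_expression <- function(ct_tbl, eff = 2) {
  assert_columns(ct_tbl, c("sample", "system", "ct"), "ct_tbl")
  if (nrow(ct_tbl) == 0L) abort("empty Ct table")
  if (any(!is.finite(ct_tbl$ct))) abort("Ct values must be finite; apply ceilings first")
  eff_tbl <- if (is.data.frame(eff)) {
    assert_columns(eff, c("system", "eff"), "eff")
    eff
  } else {
    tibble(system = unique(ct_tbl$system), eff = as.numeric(eff))
  }
  if (any(eff_tbl$eff <= 1 | eff_tbl$eff > 2.2)) {
    abort("efficiencies must lie in (1, 2.2]")
  }
  missing <- setdiff(unique(ct_tbl$system), eff_tbl$system)
  if (length(missing) > 0L) {
    abort(sprintf("no efficiency for system(s): %s", paste(missing, collapse = ", ")))
  }
  ct_tbl |>
    left_join(eff_tbl, by = "system") |>
    group_by(.data$system) |>
    mutate(ct_min = min(.data$ct), re = .data$eff^(.data$ct_min - .data$ct)) |>
    ungroup()
}

#' Normalize relative expression by housekeeping geometric mean
#'
#' Divides each sample's RE values by the geometric mean of that sample's
#' housekeeping-gene REs (G6PD, GAPDH and HPRT by default). Samples with a
#' censored or non-positive housekeeping RE cannot be normalized reliably
#' and are excluded with a message; excluded sample ids are recorded in the
#' `excluded_samples` attribute.
#'
#' @param expr output of [relative_expression()].
#' @param housekeeping character vector of housekeeping system names.
#' @return `expr` with a `norm_re` column; housekeeping rows retain their
#'   own normalized values.
#' @export
normalize_housekeeping <- function(expr,
                                   housekeeping = c("G6PD", "GAPDH", "HPRT")) {
  assert_columns(expr, c("sample", "system", "re"), "expr")
  present <- intersect(housekeeping, unique(expr$system))
  if (length(present) != length(housekeeping)) {
    abort(sprintf(
      "housekeeping system(s) absent from the table: %s",
      paste(setdiff(housekeeping, present), collapse = ", ")
    ))
  }
  hk <- expr |>
    filter(.data$system %in% housekeeping) |>
    group_by(.data$sample) |>
    summarise(
      hk_ok = all(.data$re > 0) && !any(dplyr::coalesce(.data$censored, FALSE)) &&
        dplyr::n() == length(housekeeping),
      hk_geomean = if (all(.data$re > 0)) geometric_mean(.data$re) else NA_real_,
      .groups = "drop"
    )
  excluded <- hk$sample[!hk$hk_ok]
  if (length(excluded) > 0L) {
    inform(sprintf(
      "excluding %d sample(s) with censored or invalid housekeeping expression: %s",
      length(excluded), paste(head(excluded, 5), collapse = ", ")
    ))
  }
  out <- expr |>
    inner_join(hk |> filter(.data$hk_ok) |> select("sample", "hk_geomean"), by = "sample") |>
    mutate(norm_re = .data$re / .data$hk_geomean) |>
    select(-"hk_geomean")
  attr(out, "excluded_samples") <- excluded
  out
}

#' Rescale normalized expression so the series minimum is 1
#'
#' Within each assay system, divides all normalized RE values by the lowest
#' positive value of the series, so the least-expressed sample sits exactly
#' at 1 and every other value scales up. Idempotent.
#'
#' @param expr output of [normalize_housekeeping()].
#' @param value column to scale (default `norm_re`).
#' @return `expr` with a `scaled_re` column.
#' @export
scale_to_min <- function(expr, value = "norm_re") {
  assert_columns(expr, c("system", value), "expr")
  v <- expr[[value]]
  if (all(v <= 0 | !is.finite(v))) abort("no positive values to scale")
  expr |>
    group_by(.data$system) |>
    mutate(scaled_re = {
      pos <- .data[[value]][.data[[value]] > 0]
      if (length(pos) == 0L) abort("a system has no positive values to scale")
      .data[[value]] / min(pos)
    }) |>
    ungroup()
}

#' Full relative-quantification pipeline
#'
#' Chains [apply_ct_ceiling()], [relative_expression()],
#' [normalize_housekeeping()] and [scale_to_min()].
#'
#' @inheritParams apply_ct_ceiling
#' @inheritParams relative_expression
#' @inheritParams normalize_housekeeping
#' @return A tibble with layers `ct`, `re`, `norm_re` and `scaled_re` as
#'   columns, one row per reaction.
#' @export
quantify_expression <- function(ct_tbl, annotations, ceilings, eff = 2,
                                housekeeping = c("G6PD", "GAPDH", "HPRT")) {
  ct_tbl |>
    apply_ct_ceiling(annotations, ceilings) |>
    relative_expression(eff = eff) |>
    normalize_housekeeping(housekeeping = housekeeping) |>
    scale_to_min()
}
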