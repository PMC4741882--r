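# internal helpers shared across modules

#' Geometric mean
#'
#' @param x numeric vector of positive values.
#' @param na.rm drop missing values before averaging.
#' @return The geometric mean as a scalar.
#' @examples
#' geometric_mean(c(2, 4, 8)) # 4
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) abort("cannot take the geometric mean of an empty vector")
  if (any(x <= 0)) abort("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Preferred over the Wald interval for the small strata that arise when
#' panels are evaluated on adenoma or metastasis subsets.
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return A named numeric vector `c(estimate, lower, upper)`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(estimate = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Significance star coding
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, otherwise `ns`.
#' Boundaries are strict: p equal to 0.05 is `ns`.
#'
#' @param p vector of p-values.
#' @return Character vector of the same length.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

# offset (in units of the slope parameter s) between the midpoint of a
# logistic amplification curve and the maximum of its second derivative:
# the third derivative of A/(1+exp(-(c-m)/s)) vanishes at m - s*log(2+sqrt(3))
sdm_offset <- log(2 + sqrt(3))

assert_columns <- function(df, cols, arg = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "`%s` is missing required column(s): %s",
      arg, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_probability <- function(p, what = "probability") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort(sprintf("%s values must lie in [0, 1]", what))
  }
  invisible(p)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L) abort("`seed` must be a single number")
    set.seed(as.integer(seed))
  }
  force(code)
}
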