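#' Simulate a logistic qPCR amplification curve
#'
#' Fluorescence follows `B + A / (1 + exp(-(cycle - m)/s))` plus optional
#' Gaussian noise, over 45 cycles by default. The slope parameter is tied to
#' the per-cycle amplification efficiency by `s = 1 / log(efficiency)`
#' (early-cycle growth is then proportional to `efficiency^cycle`), and the
#' midpoint `m` is placed so that the maximum of the curve's second
#' derivative — the Ct definition used throughout the package — falls
#' exactly at `target_ct`: the third derivative of the logistic vanishes at
#' `m - s * log(2 + sqrt(3))`.
#'
#' @param system,sample names carried into the output table.
#' @param target_ct cycles; where the second-derivative maximum should lie.
#'   Must be in (5, 40).
#' @param efficiency per-cycle amplification factor in (1, 2].
#' @param noise_sd SD of additive Gaussian fluorescence noise (same units as
#'   `amplitude`).
#' @param amplitude,baseline plateau height above baseline, and baseline.
#' @param n_cycles number of cycles (default 45).
#' @param seed optional integer seed.
#' @return A tibble with columns `system`, `sample`, `cycle`,
#'   `fluorescence`, carrying the generating parameters in attribute
#'   `truth` (`midpoint`, `slope`, `amplitude`, `baseline`, `target_ct`,
#'   `efficiency`).
#' @examples
#' cv <- simulate_amplification_curve("sysA", "s1", target_ct = 20, efficiency = 2)
#' sdm_ct(cv) # ~20
#' @export
simulate_amplification_curve <- function(system, sample, target_ct, efficiency,
                                         noise_sd = 0, amplitude = 1,
                                         baseline = 0.1, n_cycles = 45,
                                         seed = NULL) {
  if (!is.finite(efficiency) || efficiency <= 1) {
    abort("`efficiency` must exceed 1 (no amplification otherwise)")
  }
  if (efficiency > 2) abort("`efficiency` cannot exceed 2 (doubling per cycle)")
  if (!is.finite(target_ct) || target_ct <= 5 || target_ct >= 40) {
    abort("`target_ct` must lie in (5, 40) cycles")
  }
  if (noise_sd < 0 || amplitude <= 0) abort("invalid `noise_sd` or `amplitude`")
  with_seed(seed, {
    s <- 1 / log(efficiency)
    m <- target_ct + s * sdm_offset
    cycle <- seq_len(n_cycles)
    fl <- baseline + amplitude / (1 + exp(-(cycle - m) / s)) +
      rnorm(n_cycles, 0, noise_sd)
    out <- tibble(system = system, sample = sample, cycle = cycle, fluorescence = fl)
    attr(out, "truth") <- list(
      midpoint = m, slope = s, amplitude = amplitude, baseline = baseline,
      target_ct = target_ct, efficiency = efficiency
    )
    out
  })
}
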