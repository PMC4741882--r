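# Independent oracles used across the suite. These deliberately duplicate
# arithmetic with the most direct formulation available (closed forms,
# brute-force enumeration, per-base counting) and never call the package
# functions they check.

# logistic amplification curve built from the closed form; the maximum of
# the second derivative of B + A/(1+exp(-(c-m)/s)) lies at m - s*log(2+sqrt(3))
oracle_logistic <- function(target_ct, efficiency, amplitude = 1, baseline = 0.1,
                            noise_sd = 0, n_cycles = 45) {
  s <- 1 / log(efficiency)
  m <- target_ct + s * log(2 + sqrt(3))
  cyc <- seq_len(n_cycles)
  tibble::tibble(
    cycle = cyc,
    fluorescence = baseline + amplitude / (1 + exp(-(cyc - m) / s)) +
      stats::rnorm(n_cycles, 0, noise_sd)
  )
}

# dense-grid argmax of the analytic second derivative of a noiseless logistic
oracle_sdm_bruteforce <- function(m, s, lo = 1, hi = 45, step = 1e-4) {
  g <- seq(lo, hi, by = step)
  x <- (g - m) / s
  sig <- 1 / (1 + exp(-x))
  d2 <- sig * (1 - sig) * (1 - 2 * sig) / s^2
  g[which.max(d2)]
}

# textbook Welch statistic and Welch-Satterthwaite p-value
oracle_welch <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

# exact two-sided Mann-Whitney p-value by complete enumeration of the
# C(n_x + n_y, n_x) assignments of ranks to group x (tie-free data only)
oracle_mw_exact <- function(x, y) {
  n <- length(x)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  all_u <- apply(utils::combn(length(x) + length(y), n), 2, function(idx) {
    sum(seq_len(length(x) + length(y))[idx]) - n * (n + 1) / 2
  })
  # two-sided: double the smaller tail (the convention of exact rank tests)
  n_total <- length(all_u)
  lower <- sum(all_u <= u_obs) / n_total
  upper <- sum(all_u >= u_obs) / n_total
  min(1, 2 * min(lower, upper))
}

# per-base brute-force overlap between [qs, qe) and a set of [s, e) peaks
oracle_overlap_bruteforce <- function(qs, qe, starts, ends, chrom_len = 10000) {
  covered <- rep(FALSE, chrom_len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) covered[(starts[i] + 1):ends[i]] <- TRUE
  }
  query <- rep(FALSE, chrom_len)
  query[(qs + 1):qe] <- TRUE
  sum(covered & query)
}

# brute-force panel confusion matrix: loop over samples and members
oracle_panel_counts <- function(calls, annotations, members, case_class, control_class) {
  tp <- fp <- tn <- fn <- 0L
  for (smp in unique(calls$sample)) {
    cls <- annotations$tissue_class[annotations$sample == smp]
    if (!cls %in% c(case_class, control_class)) next
    pos <- FALSE
    for (mb in members) {
      v <- calls$positive[calls$sample == smp & calls$system == mb]
      if (length(v) == 1L && v) pos <- TRUE
    }
    if (cls == case_class && pos) tp <- tp + 1L
    if (cls == case_class && !pos) fn <- fn + 1L
    if (cls == control_class && pos) fp <- fp + 1L
    if (cls == control_class && !pos) tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# direct (non-pipeline) evaluation of the full relative-quantification chain
oracle_quant_direct <- function(ct, system, sample, eff_by_system, hk_systems) {
  re <- numeric(length(ct))
  for (sys in unique(system)) {
    sel <- system == sys
    re[sel] <- eff_by_system[[sys]]^(min(ct[sel]) - ct[sel])
  }
  hk_gm <- sapply(unique(sample), function(smp) {
    exp(mean(log(re[sample == smp & system %in% hk_systems])))
  })
  norm <- re / hk_gm[sample]
  scaled <- numeric(length(norm))
  for (sys in unique(system)) {
    sel <- system == sys
    scaled[sel] <- norm[sel] / min(norm[sel][norm[sel] > 0])
  }
  scaled
}

# minimal valid cohort pieces for hand-built tests
tiny_systems <- function() {
  tibble::tibble(
    system = c("targetA", "G6PD", "GAPDH", "HPRT"),
    role = c("target", "housekeeping", "housekeeping", "housekeeping")
  )
}

tiny_positivity <- function(p_tumor = 1, p_normal = 0) {
  tibble::tibble(
    system = "targetA", p_tumor = p_tumor, p_normal = p_normal,
    msi_or = 1, n_or = 1
  )
}
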