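#' Hit-calling thresholds
#'
#' The composite criteria a compound must satisfy to be called an analgesic
#' hit on the MEA screen: normalised activity below 50% of baseline, an
#' FDR-corrected paired Wilcoxon p below .01, |robust z'| above 1.96, a
#' large Cohen's d (|d| > 0.80), and at least 9 active channels. An optional
#' extra criterion requires the median separation to be at least 2 pooled
#' MADs; it is off by default and enabled via `fig3_mode` in [call_hit()].
#'
#' @param max_normalised_activity Maximum normalised activity, % (default 50).
#' @param max_p_fdr Maximum FDR-adjusted p value (default .01).
#' @param z_cut Robust z' magnitude cut (default 1.96).
#' @param d_cut Cohen's d magnitude cut (default 0.80).
#' @param min_active Minimum number of active channels (default 9).
#' @param min_median_sep_mads Median-separation criterion in pooled MAD
#'   units (default 2; only applied in `fig3_mode`).
#' @return An object of class `"hit_thresholds"`.
#' @export
hit_thresholds <- function(max_normalised_activity = 50, max_p_fdr = 0.01,
                           z_cut = 1.96, d_cut = 0.80, min_active = 9,
                           min_median_sep_mads = 2) {
  stopifnot(max_normalised_activity > 0, max_p_fdr > 0, z_cut > 0,
            d_cut > 0, min_active > 0, min_median_sep_mads > 0)
  structure(list(max_normalised_activity = max_normalised_activity,
                 max_p_fdr = max_p_fdr, z_cut = z_cut, d_cut = d_cut,
                 min_active = min_active,
                 min_median_sep_mads = min_median_sep_mads),
            class = "hit_thresholds")
}

#' Normalised activity after compound exposure
#'
#' Ratio of mean firing frequencies after/before treatment, expressed as a
#' percentage: `100 * mean(after) / mean(before)`.
#'
#' @param rates_before,rates_after Paired per-channel mean firing rates, Hz.
#' @return Percentage of baseline activity, or `NA` (with a warning) when
#'   the baseline mean is zero and the quantity is undefined.
#' @export
normalised_activity <- function(rates_before, rates_after) {
  stopifnot(length(rates_before) == length(rates_after),
            length(rates_before) > 0L)
  mb <- mean(rates_before)
  if (mb <= 0) {
    warning("baseline mean rate is 0; normalised activity undefined")
    return(NA_real_)
  }
  100 * mean(rates_after) / mb
}

#' Paired Wilcoxon signed-rank p value
#'
#' Two-sided signed-rank test on paired before/after rate lists, using the
#' zero-exclusion convention (channels with identical rates in the two
#' phases drop out of the test). When every difference is zero the p value
#' is 1 by definition.
#'
#' The p value is exact: the null distribution of the positive-rank sum
#' over all `2^n` sign assignments is built by dynamic programming on the
#' (mid)ranks, so ties in the rate differences are handled without falling
#' back to a normal approximation. Two-sided p is twice the smaller tail,
#' capped at 1. Beyond 300 informative pairs the asymptotic test is used.
#'
#' @param rates_before,rates_after Paired per-channel rates, Hz.
#' @return Two-sided p value.
#' @export
paired_wilcoxon <- function(rates_before, rates_after) {
  stopifnot(length(rates_before) == length(rates_after),
            length(rates_before) > 0L)
  d <- rates_after - rates_before
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  if (n > 300L)
    return(suppressWarnings(
      stats::wilcox.test(d, mu = 0, alternative = "two.sided")$p.value))
  r <- rank(abs(d)) # midranks under ties
  ir <- as.integer(round(2 * r)) # doubled ranks are integers
  # P(W+ = w) over equiprobable sign flips, by convolution
  f <- numeric(sum(ir) + 1L)
  f[1L] <- 1
  len <- length(f)
  for (k in ir) {
    g <- f
    g[(k + 1L):len] <- g[(k + 1L):len] + f[seq_len(len - k)]
    f <- g / 2
  }
  w2 <- as.integer(round(2 * sum(r[d > 0])))
  lo <- sum(f[seq_len(w2 + 1L)])
  hi <- sum(f[(w2 + 1L):len])
  min(1, 2 * min(lo, hi))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment of one p value per compound, across the screened
#' library.
#'
#' @param p_values Raw p values in `[0, 1]`.
#' @return Adjusted p values (monotone, each >= the raw value).
#' @export
fdr_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

.raw_mad <- function(x) stats::mad(x, constant = 1)

#' Robust z' effect size
#'
#' The screen's robust standardised effect size: the difference in medians
#' between the after and before rate lists divided by the pooled median
#' absolute deviation, `sqrt((MAD_before^2 + MAD_after^2)/2)` with raw
#' (unscaled) MADs. A nonparametric analogue of the classical z-score,
#' expressed in MAD units; distinct from the assay-quality z-prime of
#' high-throughput screening.
#'
#' @param rates_before,rates_after Per-channel rates, Hz (need not be equal
#'   length for the statistic itself, though the screen always pairs them).
#' @return Robust z'; signed infinity (with a warning) if both MADs are zero
#'   while the medians differ, 0 if the full configuration is degenerate but
#'   the medians agree.
#' @export
robust_z <- function(rates_before, rates_after) {
  stopifnot(length(rates_before) > 0L, length(rates_after) > 0L)
  dm <- stats::median(rates_after) - stats::median(rates_before)
  pooled <- sqrt((.raw_mad(rates_before)^2 + .raw_mad(rates_after)^2) / 2)
  if (pooled == 0) {
    if (dm == 0) return(0)
    warning("pooled MAD is 0 with unequal medians; robust z' is infinite")
    return(sign(dm) * Inf)
  }
  dm / pooled
}

#' Cohen's d effect size
#'
#' Classical two-sample Cohen's d: difference of means divided by the pooled
#' standard deviation (pooled-variance form with `n1 + n2 - 2` denominator).
#'
#' @param rates_before,rates_after Per-channel rates, Hz; each list needs at
#'   least 2 values.
#' @return Cohen's d; 0 if the pooled SD is zero with equal means, signed
#'   infinity (with a warning) otherwise.
#' @export
cohen_d <- function(rates_before, rates_after) {
  n1 <- length(rates_before); n2 <- length(rates_after)
  stopifnot(n1 >= 2L, n2 >= 2L)
  dmean <- mean(rates_after) - mean(rates_before)
  sp2 <- ((n1 - 1) * stats::var(rates_before) +
          (n2 - 1) * stats::var(rates_after)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (dmean == 0) return(0)
    warning("pooled SD is 0 with unequal means; Cohen's d is infinite")
    return(sign(dmean) * Inf)
  }
  dmean / sqrt(sp2)
}

#' Per-compound screen metrics
#'
#' Assembles the before/after statistics for one compound from its paired
#' per-channel rates. Only channels active at baseline (rate strictly above
#' the 0.33 Hz cut-off before compound application) enter the paired lists;
#' `n_active` counts them. The FDR-adjusted p is filled in across the
#' library by [screen_library()] and is `NA` here.
#'
#' @param compound_id Compound label.
#' @param rates_before,rates_after Paired per-channel rates, Hz, in matching
#'   channel order.
#' @param cfg A [detector_config()] supplying the active-channel cut-off.
#' @return An object of class `"screen_metrics"`: a list with the paired
#'   (baseline-active) rate lists, `normalised_activity`, `p_raw`, `p_fdr`
#'   (`NA` until library-level adjustment), `robust_z`, `cohen_d`,
#'   `n_active` and `median_separation_mads`.
#' @export
screen_metrics <- function(compound_id, rates_before, rates_after,
                           cfg = detector_config()) {
  stopifnot(length(rates_before) == length(rates_after))
  act <- classify_active(rates_before, cfg)
  b <- rates_before[act]; a <- rates_after[act]
  n_active <- sum(act)
  if (n_active < 2L) {
    # too few baseline-active channels for any effect statistic
    return(structure(list(compound_id = compound_id, rates_before = b,
                          rates_after = a,
                          normalised_activity = NA_real_, p_raw = NA_real_,
                          p_fdr = NA_real_, robust_z = NA_real_,
                          cohen_d = NA_real_, n_active = n_active,
                          median_separation_mads = NA_real_),
                     class = "screen_metrics"))
  }
  z <- robust_z(b, a)
  structure(list(compound_id = compound_id,
                 rates_before = b, rates_after = a,
                 normalised_activity = normalised_activity(b, a),
                 p_raw = paired_wilcoxon(b, a), p_fdr = NA_real_,
                 robust_z = z, cohen_d = cohen_d(b, a),
                 n_active = n_active,
                 median_separation_mads = abs(z)),
            class = "screen_metrics")
}

#' @export
print.screen_metrics <- function(x, ...) {
  cat(sprintf(paste0("<screen_metrics %s: activity %.3g%%, p %.3g ",
                     "(FDR %.3g), z' %.3g, d %.3g, n_active %d>\n"),
              x$compound_id, x$normalised_activity, x$p_raw, x$p_fdr,
              x$robust_z, x$cohen_d, x$n_active))
  invisible(x)
}

#' Composite hit call and intensity tier
#'
#' Applies the composite hit criteria to one compound's metrics and, for
#' hits, grades the intensity of the firing-rate reduction `r = 100 -
#' normalised activity`: high for `r > 90`, moderate for `70 < r <= 90`,
#' low for `50 < r <= 70`.
#'
#' @param m A [screen_metrics()] with `p_fdr` filled in.
#' @param t A [hit_thresholds()].
#' @param fig3_mode Logical; additionally require the median-separation
#'   criterion (>= `min_median_sep_mads` pooled MADs).
#' @return An object of class `"hit_call"`: list with `compound_id`,
#'   `is_hit`, `tier` (`"high"`, `"moderate"`, `"low"` or `"none"`) and
#'   `failed_criteria` (character vector naming every unmet rule).
#' @export
call_hit <- function(m, t = hit_thresholds(), fig3_mode = FALSE) {
  stopifnot(inherits(m, "screen_metrics"))
  failed <- character(0)
  vals <- c(m$normalised_activity, m$p_fdr, m$robust_z, m$cohen_d)
  if (anyNA(vals)) {
    failed <- "metrics_unavailable"
  } else {
    if (!(m$normalised_activity < t$max_normalised_activity))
      failed <- c(failed, "max_normalised_activity")
    if (!(m$p_fdr < t$max_p_fdr)) failed <- c(failed, "max_p_fdr")
    if (!(abs(m$robust_z) > t$z_cut)) failed <- c(failed, "z_cut")
    if (!(abs(m$cohen_d) > t$d_cut)) failed <- c(failed, "d_cut")
  }
  if (!(m$n_active >= t$min_active)) failed <- c(failed, "min_active")
  if (fig3_mode &&
      !(isTRUE(m$median_separation_mads >= t$min_median_sep_mads)))
    failed <- c(failed, "min_median_sep_mads")
  is_hit <- length(failed) == 0L
  tier <- "none"
  if (is_hit) {
    r <- 100 - m$normalised_activity
    tier <- if (r > 90) "high" else if (r > 70) "moderate" else "low"
  }
  structure(list(compound_id = m$compound_id, is_hit = is_hit, tier = tier,
                 failed_criteria = failed),
            class = "hit_call")
}

#' @export
print.hit_call <- function(x, ...) {
  if (x$is_hit) {
    cat(sprintf("<hit_call %s: HIT, %s intensity>\n", x$compound_id, x$tier))
  } else {
    cat(sprintf("<hit_call %s: not a hit (failed: %s)>\n", x$compound_id,
                paste(x$failed_criteria, collapse = ", ")))
  }
  invisible(x)
}

#' Screen a compound library from a plate rate table
#'
#' Pairs baseline and post-compound rates per channel for every compound,
#' computes the per-compound metrics, adjusts the Wilcoxon p values across
#' the library (Benjamini-Hochberg), and applies the composite hit call.
#'
#' @param rates A rate table as returned by [plate_rates()] (columns `well`,
#'   `electrode`, `phase`, `rate_hz`).
#' @param platemap Data frame mapping wells to compounds: columns `well`,
#'   `compound_id` (and optionally `concentration`).
#' @param thresholds A [hit_thresholds()].
#' @param cfg A [detector_config()].
#' @param fig3_mode Passed to [call_hit()].
#' @return A data frame, one row per compound, with the metric columns plus
#'   `is_hit`, `tier` and `failed_criteria`; the underlying
#'   `screen_metrics` objects are attached as attribute `"metrics"`.
#' @export
screen_library <- function(rates, platemap, thresholds = hit_thresholds(),
                           cfg = detector_config(), fig3_mode = FALSE) {
  stopifnot(all(c("well", "electrode", "phase", "rate_hz") %in% names(rates)),
            all(c("well", "compound_id") %in% names(platemap)))
  metrics <- list()
  for (cmpd in unique(platemap$compound_id)) {
    wells <- platemap$well[platemap$compound_id == cmpd]
    sub <- rates[rates$well %in% wells, ]
    key <- paste(sub$well, sub$electrode)
    before <- sub[sub$phase == "baseline", ]
    after <- sub[sub$phase == "post", ]
    after <- after[match(paste(before$well, before$electrode),
                         paste(after$well, after$electrode)), ]
    metrics[[cmpd]] <- screen_metrics(cmpd, before$rate_hz, after$rate_hz,
                                      cfg)
  }
  praw <- vapply(metrics, function(m) m$p_raw, numeric(1))
  padj <- rep(NA_real_, length(praw))
  ok <- !is.na(praw)
  padj[ok] <- fdr_adjust(praw[ok])
  out <- list()
  for (i in seq_along(metrics)) {
    metrics[[i]]$p_fdr <- padj[i]
    hc <- call_hit(metrics[[i]], thresholds, fig3_mode)
    m <- metrics[[i]]
    out[[i]] <- data.frame(
      compound_id = m$compound_id,
      normalised_activity = m$normalised_activity,
      p_raw = m$p_raw, p_fdr = m$p_fdr, robust_z = m$robust_z,
      cohen_d = m$cohen_d, n_active = m$n_active,
      median_separation_mads = m$median_separation_mads,
      is_hit = hc$is_hit, tier = hc$tier,
      failed_criteria = paste(hc$failed_criteria, collapse = ";"))
  }
  res <- do.call(rbind, out)
  attr(res, "metrics") <- metrics
  res
}
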