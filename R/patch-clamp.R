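#' A patch-clamp sweep
#'
#' One recorded sweep: membrane voltage (mV, current-clamp) or membrane
#' current (pA, voltage-clamp) sampled uniformly in time, together with the
#' protocol it came from and, for stepped protocols, the step schedule.
#'
#' @param time Time base, s (uniformly sampled).
#' @param value Voltage (mV) or current (pA) samples, same length as `time`.
#' @param protocol `"gapfree"`, `"current_step"` or `"voltage_step"`.
#' @param step_schedule Optional data frame with columns `level`, `onset`
#'   (s) and `duration` (s), one row per commanded segment, required for the
#'   stepped protocols.
#' @return An object of class `"patch_sweep"` with the sampling rate (`fs`)
#'   derived from the time base.
#' @export
patch_sweep <- function(time, value,
                        protocol = c("gapfree", "current_step",
                                     "voltage_step"),
                        step_schedule = NULL) {
  protocol <- match.arg(protocol)
  stopifnot(length(time) == length(value), length(time) > 1L)
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-9 * stats::median(dt) + 1e-12)
    stop("sweep must be uniformly sampled")
  if (!is.null(step_schedule)) {
    stopifnot(all(c("level", "onset", "duration") %in% names(step_schedule)))
    if (max(step_schedule$onset + step_schedule$duration) >
        max(time) + stats::median(dt))
      stop("step schedule extends beyond sweep duration")
  }
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 protocol = protocol, step_schedule = step_schedule,
                 fs = 1 / stats::median(dt)),
            class = "patch_sweep")
}

#' @export
print.patch_sweep <- function(x, ...) {
  cat(sprintf("<patch_sweep [%s]: %d samples @ %g Hz (%.3g s)>\n",
              x$protocol, length(x$value), x$fs, max(x$time)))
  invisible(x)
}

## Savitzky-Golay smooth / derivative of a sweep value series.
## m = derivative order; output is in mV per ms^m for voltage sweeps.
.sg <- function(v, fs, m = 0, window_ms = 1, p = 5) {
  n <- max(p + 2, round(window_ms / 1000 * fs))
  if (n %% 2 == 0) n <- n + 1
  out <- signal::sgolayfilt(v, p = p, n = n, m = m, ts = 1 / fs)
  out / 1000^m # per second^m -> per ms^m
}

#' Locate spike-like events in a current-clamp sweep
#'
#' Events are found on the rate of rise: the Savitzky-Golay smoothed first
#' derivative must exceed `dvdt_min` (default 10 mV/ms). A derivative
#' criterion, unlike a voltage threshold, also catches "attempting" events
#' whose peaks stay below 0 mV. Each event is reported with its onset and
#' the voltage peak reached before the next event (or within `peak_win_ms`).
#'
#' @param sweep A current-clamp [patch_sweep()].
#' @param dvdt_min Rate-of-rise criterion, mV/ms.
#' @param min_gap_ms Minimum separation between event onsets, ms.
#' @param peak_win_ms Window after onset searched for the peak, ms.
#' @param smooth_ms Width of the derivative smoothing window, ms (default
#'   2; wide enough that sub-millivolt recording noise stays well below the
#'   rate-of-rise criterion).
#' @return Data frame with columns `onset_idx`, `onset_s`, `peak_idx`,
#'   `peak_mV`; zero rows when the sweep is quiet.
#' @export
detect_patch_events <- function(sweep, dvdt_min = 10, min_gap_ms = 2,
                                peak_win_ms = 10, smooth_ms = 2) {
  stopifnot(inherits(sweep, "patch_sweep"))
  v <- sweep$value; fs <- sweep$fs
  d1 <- .sg(v, fs, m = 1, window_ms = smooth_ms, p = 3)
  fast <- d1 >= dvdt_min
  cross <- which(fast & !c(FALSE, fast[-length(fast)]))
  gap <- round(min_gap_ms / 1000 * fs)
  keep <- integer(0); last <- -Inf
  for (i in cross) {
    if (i - last >= gap) { keep <- c(keep, i); last <- i }
  }
  if (length(keep) == 0L)
    return(data.frame(onset_idx = integer(0), onset_s = numeric(0),
                      peak_idx = integer(0), peak_mV = numeric(0)))
  win <- round(peak_win_ms / 1000 * fs)
  ends <- c(keep[-1L] - 1L, length(v))
  peak_idx <- integer(length(keep)); peak_mV <- numeric(length(keep))
  for (j in seq_along(keep)) {
    to <- min(keep[j] + win, ends[j], length(v))
    seg <- keep[j]:to
    peak_idx[j] <- seg[which.max(v[seg])]
    peak_mV[j] <- v[peak_idx[j]]
  }
  data.frame(onset_idx = keep, onset_s = (keep - 1L) / fs,
             peak_idx = peak_idx, peak_mV = peak_mV)
}

#' Resting membrane potential from a gap-free sweep
#'
#' Mean voltage over the first 30 s of the sweep, with spike samples masked
#' out: samples belonging to detected events (onset to 20 ms after onset)
#' are excluded so that spontaneous spikes do not bias the estimate.
#'
#' @param sweep A gap-free current-clamp [patch_sweep()].
#' @param window_s Averaging window, s (default 30; a shorter sweep is used
#'   in full with a warning).
#' @param ... Passed to [detect_patch_events()].
#' @return Resting membrane potential, mV.
#' @export
resting_vm <- function(sweep, window_s = 30, ...) {
  stopifnot(inherits(sweep, "patch_sweep"))
  fs <- sweep$fs
  n <- length(sweep$value)
  n_win <- round(window_s * fs)
  if (n < n_win) {
    warning(sprintf("sweep shorter than %g s; using full length", window_s))
    n_win <- n
  }
  v <- sweep$value[seq_len(n_win)]
  ev <- detect_patch_events(sweep, ...)
  mask <- rep(TRUE, n_win)
  if (nrow(ev) > 0L) {
    pad <- round(0.020 * fs)
    for (i in seq_len(nrow(ev))) {
      from <- max(1L, ev$onset_idx[i] - round(0.002 * fs))
      to <- min(n_win, ev$onset_idx[i] + pad)
      if (from <= n_win) mask[from:to] <- FALSE
    }
  }
  mean(v[mask])
}

#' Classify spontaneous activity in a gap-free sweep
#'
#' Three-way classification of 60 s gap-free current-clamp recordings:
#' `"quiet"` (no spike-like events), `"attempting_sap"` (events present but
#' no peak reaches 0 mV), `"spontaneous"` (at least one overshooting spike
#' with peak >= 0 mV).
#'
#' @param sweep A gap-free [patch_sweep()].
#' @param ... Passed to [detect_patch_events()].
#' @return One of `"quiet"`, `"attempting_sap"`, `"spontaneous"`.
#' @export
classify_gapfree <- function(sweep, ...) {
  ev <- detect_patch_events(sweep, ...)
  if (nrow(ev) == 0L) return("quiet")
  if (any(ev$peak_mV >= 0)) "spontaneous" else "attempting_sap"
}

#' Classify the response to a current-step family
#'
#' Classifies induced activity over a family of 1 s current steps (ordered
#' by injected current, -10 to 180 pA): `"train"` when any step elicits at
#' least 3 complete spikes (peak >= 0 mV); `"single_iap"` when the best step
#' elicits 1-2 complete spikes; `"attempting_train"` / `"attempting_single"`
#' when events occur but never reach 0 mV (3+ vs fewer events at the best
#' step); `"quiet"` when no step elicits any event.
#'
#' @param sweeps List of current-clamp [patch_sweep()]s, one per step.
#' @param ... Passed to [detect_patch_events()].
#' @return One of the five class labels.
#' @export
classify_current_step <- function(sweeps, ...) {
  if (length(sweeps) == 0L) stop("empty current-step family")
  n_complete <- integer(length(sweeps))
  n_events <- integer(length(sweeps))
  for (i in seq_along(sweeps)) {
    ev <- detect_patch_events(sweeps[[i]], ...)
    n_events[i] <- nrow(ev)
    n_complete[i] <- sum(ev$peak_mV >= 0)
  }
  if (max(n_complete) >= 3L) return("train")
  if (max(n_complete) >= 1L) return("single_iap")
  if (max(n_events) >= 3L) return("attempting_train")
  if (max(n_events) >= 1L) return("attempting_single")
  "quiet"
}

#' Action-potential parameters for one spike
#'
#' Extracts the standard AP feature set for the `spike_index`-th detected
#' event. Derivatives are taken on a Savitzky-Golay local-polynomial smooth
#' (order 5; 1 ms window for the smooth and first derivative, 3 ms for the
#' third derivative, whose noise gain is far steeper). Definitions: threshold = voltage at the peak of the third
#' derivative during the depolarising phase; spike height = peak voltage
#' minus threshold; overshoot = peak voltage (mV relative to 0);
#' after-hyperpolarisation = post-peak minimum minus threshold;
#' depolarising/repolarising rates = extrema of dV/dt around the peak;
#' half-height width = duration at threshold + height/2.
#'
#' @param sweep A current-clamp [patch_sweep()].
#' @param spike_index Which detected event to measure (default 1).
#' @param pre_ms,post_ms Analysis window around the peak, ms.
#' @param ... Passed to [detect_patch_events()].
#' @return An object of class `"ap_parameters"`: list with `overshoot`,
#'   `after_hyperpolarisation`, `depolarising_rate`, `repolarising_rate`,
#'   `spike_height`, `half_height_width` (ms), `threshold`, `peak_mV`,
#'   `resting_vm` and an `incomplete` flag (set when the analysis window is
#'   truncated at a sweep edge).
#' @export
spike_parameters <- function(sweep, spike_index = 1L, pre_ms = 5,
                             post_ms = 20, ...) {
  ev <- detect_patch_events(sweep, ...)
  if (nrow(ev) < spike_index) stop("no such spike in sweep")
  fs <- sweep$fs
  peak <- ev$peak_idx[spike_index]
  n <- length(sweep$value)
  from <- peak - round(pre_ms / 1000 * fs)
  to <- peak + round(post_ms / 1000 * fs)
  incomplete <- from < 1L || to > n
  from <- max(1L, from); to <- min(n, to)
  vs <- .sg(sweep$value, fs, m = 0)
  d1 <- .sg(sweep$value, fs, m = 1)
  # derivative noise gain grows steeply with order: the third derivative
  # needs a wider local-polynomial support than the smooth/first derivative
  d3 <- .sg(sweep$value, fs, m = 3, window_ms = 3)

  # search for the third-derivative peak near the spike foot: around the
  # dV/dt onset, restricted to the depolarising phase, so distant noise
  # excursions cannot masquerade as the threshold
  onset <- ev$onset_idx[spike_index]
  half_win <- round(0.001 * fs)
  rise <- max(from, onset - half_win):min(peak, onset + half_win)
  rise <- rise[d1[rise] > 0]
  if (length(rise) < 3L) rise <- from:peak
  thr_idx <- rise[which.max(d3[rise])]
  threshold <- vs[thr_idx]
  peak_mV <- vs[peak]
  height <- peak_mV - threshold

  post <- peak:to
  ahp <- min(vs[post]) - threshold
  dep_rate <- max(d1[from:peak])
  rep_rate <- min(d1[post])

  # half-height width by linear interpolation of the level crossings
  level <- threshold + height / 2
  w <- NA_real_
  lo_seg <- vs[from:peak]; hi_seg <- vs[peak:to]
  i_up <- which(lo_seg < level)
  i_dn <- which(hi_seg < level)
  if (length(i_up) > 0L && length(i_dn) > 0L) {
    iu <- max(i_up) # last sub-level sample on the rise
    t_up <- (from + iu - 1L) +
      (level - lo_seg[iu]) / (lo_seg[iu + 1L] - lo_seg[iu])
    id <- min(i_dn) # first sub-level sample on the fall
    t_dn <- (peak + id - 2L) +
      (level - hi_seg[id - 1L]) / (hi_seg[id] - hi_seg[id - 1L])
    w <- (t_dn - t_up) / fs * 1000
  } else {
    incomplete <- TRUE
  }

  structure(list(overshoot = peak_mV, after_hyperpolarisation = ahp,
                 depolarising_rate = dep_rate, repolarising_rate = rep_rate,
                 spike_height = height, half_height_width = w,
                 threshold = threshold, peak_mV = peak_mV,
                 resting_vm = stats::median(vs[seq_len(max(1L, from))]),
                 incomplete = incomplete),
            class = "ap_parameters")
}

#' @export
print.ap_parameters <- function(x, digits = 3, ...) {
  cat("Action-potential parameters",
      if (x$incomplete) "(INCOMPLETE: window truncated)" else "", "\n")
  flds <- c(overshoot = "mV", after_hyperpolarisation = "mV",
            depolarising_rate = "mV/ms", repolarising_rate = "mV/ms",
            spike_height = "mV", half_height_width = "ms",
            threshold = "mV", resting_vm = "mV")
  for (f in names(flds))
    cat(sprintf("  %-24s %8.*g %s\n", f, digits, x[[f]], flds[[f]]))
  invisible(x)
}

#' Extract Nav/Kv I-V measurements from a voltage-step family
#'
#' For each sweep of a voltage-step family (held at -70 mV, test potentials
#' -120 to +80 mV in 5 mV steps), measures relative to the pre-step holding
#' current: the Nav activation current as the most negative value in the
#' first 10 ms of the test step; the Nav inactivation current as the trough
#' in the probe segment between the test step and the recovery step (when
#' the schedule contains one); and the Kv steady-state current as the mean
#' over the final 50 ms of the test step.
#'
#' @param family List of voltage-clamp [patch_sweep()]s, each with a
#'   `step_schedule` whose second row is the test step, and an attribute or
#'   schedule level giving the test potential.
#' @param activation_win_ms Window at the start of the test step searched
#'   for the inward peak, ms.
#' @param kv_win_ms Averaging window at the end of the test step, ms.
#' @return An object of class `"iv_curve"`: list of equal-length vectors
#'   `test_potentials` (mV, increasing), `nav_activation`,
#'   `nav_inactivation`, `kv_steady` (pA, holding-subtracted).
#' @export
extract_iv <- function(family, activation_win_ms = 10, kv_win_ms = 50) {
  stopifnot(length(family) > 0L)
  n <- length(family)
  pot <- act <- inact <- kv <- numeric(n)
  for (i in seq_len(n)) {
    sw <- family[[i]]
    sch <- sw$step_schedule
    if (is.null(sch) || nrow(sch) < 2L)
      stop("voltage-step sweep lacks a step schedule")
    fs <- sw$fs; v <- sw$value
    idx <- function(t) pmin(length(v), pmax(1L, round(t * fs) + 1L))
    hold_end <- idx(sch$onset[2])
    baseline <- mean(v[seq_len(max(1L, hold_end - 1L))])
    t0 <- sch$onset[2]; t1 <- t0 + sch$duration[2]
    a_win <- idx(t0):idx(min(t1, t0 + activation_win_ms / 1000))
    act[i] <- min(v[a_win]) - baseline
    kv_from <- max(t0, t1 - kv_win_ms / 1000)
    kv[i] <- mean(v[idx(kv_from):idx(t1)]) - baseline
    inact[i] <- if (nrow(sch) >= 4L) {
      p0 <- sch$onset[3]; p1 <- p0 + sch$duration[3]
      min(v[idx(p0):idx(p1)]) - baseline
    } else NA_real_
    pot[i] <- sch$level[2]
  }
  o <- order(pot)
  structure(list(test_potentials = pot[o], nav_activation = act[o],
                 nav_inactivation = inact[o], kv_steady = kv[o]),
            class = "iv_curve")
}

#' @export
print.iv_curve <- function(x, ...) {
  cat(sprintf("<iv_curve: %d test potentials from %g to %g mV>\n",
              length(x$test_potentials), min(x$test_potentials),
              max(x$test_potentials)))
  cat(sprintf("  peak Nav activation %.4g pA at %g mV\n",
              min(x$nav_activation),
              x$test_potentials[which.min(x$nav_activation)]))
  invisible(x)
}

#' TTX-normalised inhibition fraction
#'
#' Expresses a compound's block of the Nav activation current as a fraction
#' of the TTX-sensitive current at the maximal-current test potential:
#' `(I_control - I_compound) / (I_control - I_ttx)` evaluated at -35 mV.
#'
#' @param control,compound,ttx [extract_iv()] curves sharing the test
#'   potential grid.
#' @param at Test potential, mV (default -35, the maximal Nav current step).
#' @return Inhibition fraction `dI/dI_TTX`. Values outside `[0, 1.05]` are
#'   returned as measured but carry attribute `flagged = TRUE`.
#' @export
ttx_normalised_inhibition <- function(control, compound, ttx, at = -35) {
  pick <- function(curve) {
    i <- which(curve$test_potentials == at)
    if (length(i) != 1L)
      stop(sprintf("curve lacks the %g mV test potential", at))
    curve$nav_activation[i]
  }
  ic <- pick(control); im <- pick(compound); it <- pick(ttx)
  denom <- ic - it
  if (denom == 0)
    stop("assay error: control and TTX currents are equal at ", at, " mV")
  frac <- (ic - im) / denom
  if (frac < 0 || frac > 1.05) attr(frac, "flagged") <- TRUE
  frac
}
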