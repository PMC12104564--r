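#' Specification of a synthetic MEA plate
#'
#' Describes the geometry, acquisition settings and firing statistics of a
#' simulated multiwell MEA recording. Defaults mirror the screening setup:
#' 24-well plates with 12 electrodes per well (288 channels), digitised at
#' 20 kHz, 300 s recordings per phase. Baseline firing rates are drawn
#' log-normally per channel, with an inactive fraction of channels given a
#' low sub-threshold rate so the 0.33 Hz active-channel rule is exercised on
#' both sides.
#'
#' @param n_wells Number of wells (default 24).
#' @param n_electrodes Electrodes per well (default 12).
#' @param sampling_rate Hz (default 20000).
#' @param duration Recording length per phase, s (default 300). Simulating a
#'   full default plate at trace level is memory-hungry; tests and examples
#'   use fewer wells and shorter durations.
#' @param noise_sd Gaussian noise SD, uV (default 3).
#' @param spike_amplitude Template peak amplitude, uV (default 30, i.e.
#'   10 x the default noise SD).
#' @param baseline_rate_median Median of the log-normal baseline firing-rate
#'   distribution, Hz (default 2, an elevated spontaneous rate typical of
#'   IEM patient-derived cultures).
#' @param baseline_rate_sdlog Log-scale SD of the rate distribution
#'   (default 0.5).
#' @param active_fraction Proportion of channels drawn from the active-rate
#'   distribution (default 0.85); the rest get a low rate uniform on
#'   `[0, 0.25]` Hz.
#' @param seed Integer seed; identical specs and seeds give bit-identical
#'   plates.
#' @return An object of class `"plate_spec"`.
#' @export
plate_spec <- function(n_wells = 24L, n_electrodes = 12L,
                       sampling_rate = 20000, duration = 300,
                       noise_sd = 3, spike_amplitude = 30,
                       baseline_rate_median = 2, baseline_rate_sdlog = 0.5,
                       active_fraction = 0.85, seed = 1L) {
  stopifnot(n_wells >= 1L, n_electrodes >= 1L, sampling_rate > 0,
            duration > 0, noise_sd >= 0, spike_amplitude > 0,
            baseline_rate_median > 0, baseline_rate_sdlog >= 0,
            active_fraction >= 0, active_fraction <= 1)
  structure(list(n_wells = as.integer(n_wells),
                 n_electrodes = as.integer(n_electrodes),
                 sampling_rate = sampling_rate, duration = duration,
                 noise_sd = noise_sd, spike_amplitude = spike_amplitude,
                 baseline_rate_median = baseline_rate_median,
                 baseline_rate_sdlog = baseline_rate_sdlog,
                 active_fraction = active_fraction,
                 seed = as.integer(seed)),
            class = "plate_spec")
}

#' Ground-truth pharmacology of a simulated compound
#'
#' @param compound_id Label.
#' @param ic50_true True half-maximal inhibitory concentration, uM.
#' @param hill_n_true True Hill coefficient.
#' @param toxic Logical: does the compound release LDH above threshold?
#' @param reversible Logical: does activity recover on washout?
#' @param recovery_fraction Fraction of the inhibited gap regained on
#'   washout, in `[0, 1]`; defaults to 0.9 for reversible compounds and
#'   0.05 otherwise.
#' @return An object of class `"compound_truth"`.
#' @export
compound_truth <- function(compound_id, ic50_true, hill_n_true = 2,
                           toxic = FALSE, reversible = TRUE,
                           recovery_fraction = if (reversible) 0.9 else 0.05) {
  stopifnot(ic50_true > 0, hill_n_true > 0,
            recovery_fraction >= 0, recovery_fraction <= 1)
  structure(list(compound_id = compound_id, ic50_true = ic50_true,
                 hill_n_true = hill_n_true, toxic = toxic,
                 reversible = reversible,
                 recovery_fraction = recovery_fraction),
            class = "compound_truth")
}

## Stable per-channel seed: a plate-level seed is split into independent
## substreams keyed by (well, electrode, stream), so adding wells never
## perturbs existing channels. Kept below 2^31.
.chan_seed <- function(seed, well, electrode, stream) {
  as.integer((seed + 7919 * well + 104729 * electrode +
              15485863 * stream) %% 2147483587)
}

## Poisson firing with an absolute refractory period equal to the detector
## dead time. The exponential rate is inflated so the mean ISI is exactly
## 1/rate despite the refractory offset, keeping the realised rate unbiased.
.sim_spike_times <- function(rate, duration, refractory = 0.003) {
  if (rate <= 0) return(numeric(0))
  if (rate * refractory >= 0.9)
    stop("firing rate too high for the refractory period")
  r_exp <- rate / (1 - rate * refractory)
  times <- numeric(0)
  t <- 0
  repeat {
    n_draw <- max(16L, ceiling((duration - t) * rate * 1.5))
    isi <- refractory + stats::rexp(n_draw, r_exp)
    times <- c(times, t + cumsum(isi))
    t <- times[length(times)]
    if (t > duration) break
  }
  times[times <= duration]
}

## Fixed biphasic extracellular template over a 1 ms support: a sharp
## negative-leading transient (two 0.25 ms lobes, spectral energy around
## 2 kHz, well inside the 1-10 kHz detection band) followed by a silent
## tail. Peak amplitude `amp`.
.spike_template <- function(fs, amp) {
  k <- max(8L, round(fs * 0.001))
  u <- seq(0, 1, length.out = k)
  w <- numeric(k)
  lobe <- u <= 0.5
  w[lobe] <- -amp * sin(4 * pi * u[lobe])
  w
}

.render_trace <- function(spike_times, n, fs, noise_sd, amp) {
  v <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  tpl <- .spike_template(fs, amp)
  k <- length(tpl)
  for (t in spike_times) {
    i0 <- floor(t * fs) + 1L
    i1 <- min(n, i0 + k - 1L)
    if (i0 <= n) v[i0:i1] <- v[i0:i1] + tpl[seq_len(i1 - i0 + 1L)]
  }
  v
}

.draw_baseline_rate <- function(spec) {
  if (stats::runif(1) < spec$active_fraction) {
    stats::rlnorm(1, meanlog = log(spec$baseline_rate_median),
                  sdlog = spec$baseline_rate_sdlog)
  } else {
    stats::runif(1, 0, 0.25)
  }
}

#' Simulate a multiwell MEA plate with before/after/washout phases
#'
#' Generates one synthetic plate under the screening design: every channel
#' fires as a homogeneous Poisson process (with an absolute refractory
#' period equal to the detector dead time) at a per-channel baseline rate;
#' in the post-compound phase the rate is scaled by the Hill activity model
#' under the well's compound and concentration; in the washout phase the
#' rate recovers towards baseline by the compound's `recovery_fraction`.
#' Spikes are rendered as a fixed negative-leading biphasic template (1 ms)
#' added to zero-mean Gaussian noise, and the exact spike times are kept as
#' ground truth.
#'
#' @param spec A [plate_spec()].
#' @param exposures Data frame with columns `well` (1-based index or label
#'   `W01`...), `compound_id`, `concentration` (uM, >= 0). Wells not listed
#'   receive vehicle (concentration 0).
#' @param truths Named list of [compound_truth()] objects (names =
#'   compound ids).
#' @return An object of class `"simulated_plate"`: `spec`, `exposures`,
#'   `truths` and a named `channels` list (`"W01_E01"`, ...), each channel
#'   holding its baseline rate, per-phase true rates, [channel_trace()]s and
#'   true spike times.
#' @export
simulate_plate <- function(spec, exposures, truths) {
  stopifnot(inherits(spec, "plate_spec"),
            all(c("well", "compound_id", "concentration") %in%
                names(exposures)))
  if (any(exposures$concentration < 0))
    stop("concentrations must be non-negative")
  unknown <- setdiff(exposures$compound_id, names(truths))
  if (length(unknown) > 0L)
    stop("unknown compound id(s) in exposures: ",
         paste(unknown, collapse = ", "))
  well_lab <- function(w) if (is.numeric(w)) sprintf("W%02d", w) else w
  exposures$well <- vapply(exposures$well, well_lab, character(1))
  if (anyDuplicated(exposures$well))
    stop("each well may carry at most one exposure")

  fs <- spec$sampling_rate
  n <- round(spec$duration * fs)
  phases <- c("baseline", "post", "washout")
  channels <- list()
  for (w in seq_len(spec$n_wells)) {
    wl <- sprintf("W%02d", w)
    row <- exposures[exposures$well == wl, , drop = FALSE]
    if (nrow(row) == 1L) {
      tru <- truths[[row$compound_id]]
      act <- hill_activity(row$concentration, tru$ic50_true,
                           tru$hill_n_true) / 100
      recov <- tru$recovery_fraction
    } else {
      act <- 1; recov <- 1 # vehicle well
    }
    for (e in seq_len(spec$n_electrodes)) {
      el <- sprintf("E%02d", e)
      set.seed(.chan_seed(spec$seed, w, e, 0L))
      r_base <- .draw_baseline_rate(spec)
      r <- c(baseline = r_base, post = r_base * act,
             washout = r_base * act + recov * (r_base - r_base * act))
      traces <- list(); spikes <- list()
      for (k in seq_along(phases)) {
        ph <- phases[k]
        set.seed(.chan_seed(spec$seed, w, e, k))
        st <- .sim_spike_times(r[[ph]], spec$duration)
        traces[[ph]] <- channel_trace(
          .render_trace(st, n, fs, spec$noise_sd, spec$spike_amplitude),
          fs, well_id = wl, electrode_id = el, phase = ph)
        spikes[[ph]] <- st
      }
      channels[[paste(wl, el, sep = "_")]] <-
        list(well = wl, electrode = el, baseline_rate = r_base,
             true_rates = r, traces = traces, true_spikes = spikes)
    }
  }
  structure(list(spec = spec, exposures = exposures, truths = truths,
                 channels = channels),
            class = "simulated_plate")
}

#' @export
print.simulated_plate <- function(x, ...) {
  cat(sprintf(
    "<simulated_plate: %d wells x %d electrodes, %g s/phase @ %g Hz>\n",
    x$spec$n_wells, x$spec$n_electrodes, x$spec$duration,
    x$spec$sampling_rate))
  cat(sprintf("  %d exposures over %d compounds\n", nrow(x$exposures),
              length(unique(x$exposures$compound_id))))
  invisible(x)
}

#' Simulate measured firing rates for a compound screen (rate level)
#'
#' Rate-level counterpart of [simulate_plate()] for large libraries and
#' repeated-seed studies: instead of rendering voltage traces it draws the
#' measured per-channel rates directly as Poisson counts over the recording
#' duration, under the same Hill suppression and washout-recovery model.
#' Statistically this is the quantity the detection chain delivers when the
#' detector operates near-perfectly (amplitudes well above noise).
#'
#' @param exposures Data frame with `well`, `compound_id`, `concentration`.
#' @param truths Named list of [compound_truth()]s.
#' @param n_channels Channels per well (default 12).
#' @param duration Recording duration per phase, s (default 300).
#' @param baseline_rate_median,baseline_rate_sdlog,active_fraction As in
#'   [plate_spec()].
#' @param seed Integer seed.
#' @return Data frame with one row per channel: `well`, `compound_id`,
#'   `concentration`, `electrode`, `rate_before`, `rate_after`,
#'   `rate_washout` (Hz).
#' @export
simulate_screen_rates <- function(exposures, truths, n_channels = 12L,
                                  duration = 300,
                                  baseline_rate_median = 2,
                                  baseline_rate_sdlog = 0.5,
                                  active_fraction = 1, seed = 1L) {
  stopifnot(all(exposures$concentration >= 0))
  unknown <- setdiff(exposures$compound_id, names(truths))
  if (length(unknown) > 0L)
    stop("unknown compound id(s): ", paste(unknown, collapse = ", "))
  set.seed(as.integer(seed))
  rows <- vector("list", nrow(exposures))
  for (i in seq_len(nrow(exposures))) {
    tru <- truths[[exposures$compound_id[i]]]
    act <- hill_activity(exposures$concentration[i], tru$ic50_true,
                         tru$hill_n_true) / 100
    active <- stats::runif(n_channels) < active_fraction
    r_base <- ifelse(active,
                     stats::rlnorm(n_channels,
                                   log(baseline_rate_median),
                                   baseline_rate_sdlog),
                     stats::runif(n_channels, 0, 0.25))
    r_post <- r_base * act
    r_wash <- r_post + tru$recovery_fraction * (r_base - r_post)
    draw <- function(r) stats::rpois(n_channels, r * duration) / duration
    rows[[i]] <- data.frame(
      well = exposures$well[i], compound_id = exposures$compound_id[i],
      concentration = exposures$concentration[i],
      electrode = sprintf("E%02d", seq_len(n_channels)),
      rate_before = draw(r_base), rate_after = draw(r_post),
      rate_washout = draw(r_wash))
  }
  do.call(rbind, rows)
}

#' Simulate concentration-response points for one compound
#'
#' Generates per-well normalised-activity replicates over a concentration
#' grid, each from Poisson spike counts before/after exposure, ready for
#' [fit_dose_response()] in Hill mode.
#'
#' @param truth A [compound_truth()].
#' @param concentrations Grid, uM (a tier range from [select_tier_range()]).
#' @param n_replicates Wells per concentration (default 3).
#' @param n_channels,duration,baseline_rate_median,baseline_rate_sdlog As in
#'   [simulate_screen_rates()].
#' @param seed Integer seed.
#' @return Data frame with columns `concentration`, `response` (% activity)
#'   and `replicate`.
#' @export
simulate_dose_response_points <- function(truth, concentrations,
                                          n_replicates = 3L,
                                          n_channels = 12L, duration = 300,
                                          baseline_rate_median = 2,
                                          baseline_rate_sdlog = 0.5,
                                          seed = 1L) {
  stopifnot(inherits(truth, "compound_truth"), length(concentrations) > 0L)
  set.seed(as.integer(seed))
  out <- list()
  for (conc in concentrations) {
    act <- hill_activity(conc, truth$ic50_true, truth$hill_n_true) / 100
    for (rep_i in seq_len(n_replicates)) {
      r_base <- stats::rlnorm(n_channels, log(baseline_rate_median),
                              baseline_rate_sdlog)
      before <- stats::rpois(n_channels, r_base * duration) / duration
      after <- stats::rpois(n_channels, r_base * act * duration) / duration
      out[[length(out) + 1L]] <- data.frame(
        concentration = conc,
        response = 100 * mean(after) / mean(before),
        replicate = rep_i)
    }
  }
  do.call(rbind, out)
}

#' Simulate an LDH absorbance table
#'
#' Emits vehicle-control, positive-control and per-compound absorbance
#' readings (490 nm LDH signal, 680 nm background) at the 1, 6 and 24 h
#' timepoints, with additive Gaussian read noise. Toxic compounds release
#' LDH at `toxic_fraction` of the positive-control signal (default 20%,
#' well above the 5% verdict threshold); non-toxic compounds at
#' `nontoxic_fraction` (default 1%).
#'
#' @param truths Named list of [compound_truth()]s.
#' @param seed Integer seed.
#' @param timepoints Hours post-exposure (default `c(1, 6, 24)`).
#' @param noise_sd Absorbance read noise SD (default 0.005).
#' @param toxic_fraction,nontoxic_fraction True LDH release as a fraction of
#'   the positive-control window.
#' @return Data frame with columns `compound_id`, `role` (`"sample"`,
#'   `"vehicle"`, `"positive_control"`), `timepoint_h`, `a490`, `a680`.
#' @export
simulate_ldh <- function(truths, seed = 1L, timepoints = c(1, 6, 24),
                         noise_sd = 0.005, toxic_fraction = 0.20,
                         nontoxic_fraction = 0.01) {
  set.seed(as.integer(seed))
  bg <- 0.05; veh_delta <- 0.02; pos_delta <- 1.0
  rows <- list()
  emit <- function(id, role, frac) {
    for (tp in timepoints) {
      delta <- veh_delta + frac * (pos_delta - veh_delta)
      a680 <- bg + stats::rnorm(1, 0, noise_sd)
      a490 <- bg + delta + stats::rnorm(1, 0, noise_sd)
      rows[[length(rows) + 1L]] <<- data.frame(
        compound_id = id, role = role, timepoint_h = tp,
        a490 = max(0, a490), a680 = max(0, a680))
    }
  }
  emit(NA_character_, "vehicle", 0)
  emit(NA_character_, "positive_control", 1)
  for (tru in truths)
    emit(tru$compound_id, "sample",
         if (tru$toxic) toxic_fraction else nontoxic_fraction)
  do.call(rbind, rows)
}

## Normalised double-exponential transient, peak scaled to 1.
.nav_transient <- function(t, tau_rise = 3e-4, tau_decay = 1.5e-3) {
  g <- exp(-t / tau_decay) - exp(-t / tau_rise)
  tpk <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  g / (exp(-tpk / tau_decay) - exp(-tpk / tau_rise))
}

#' Simulate a voltage-step I-V family under graded compound block
#'
#' Generates voltage-clamp current sweeps over test potentials -120 to
#' +80 mV (5 mV increments, held at -70 mV) for a control condition, an
#' optional TTX condition, and each requested compound concentration. The
#' inward Nav-like component is a difference-of-exponentials transient whose
#' voltage dependence peaks at the -35 mV step; it is scaled by
#' `1 - boltzmann_inhibition(conc, ic50, slope_h)` and set to zero under
#' TTX. The sustained outward Kv-like component is unaffected by compound
#' and TTX. Each sweep carries a 4-segment schedule (hold, test step,
#' inactivation probe, recovery) so [extract_iv()] can locate its windows.
#'
#' @param ic50 True Boltzmann midpoint of the block, uM.
#' @param slope_h True slope factor, uM.
#' @param concentrations Compound concentrations to simulate, uM; must be
#'   non-empty.
#' @param include_ttx Emit the TTX reference family (default TRUE).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param noise_sd Current noise SD, pA (default 0: noiseless).
#' @param i_max Control Nav peak magnitude at -35 mV, pA.
#' @param potentials Test potentials, mV.
#' @param fs Sampling rate, Hz.
#' @return A list with `potentials` and `conditions`, a named list of sweep
#'   families (`"control"`, `"ttx"`, `"c_<conc>"`), each a list of
#'   [patch_sweep()]s; the generating parameters are stored in `truth`.
#' @export
simulate_voltage_step_family <- function(ic50, slope_h, concentrations,
                                         include_ttx = TRUE, seed = 1L,
                                         noise_sd = 0, i_max = 500,
                                         potentials = seq(-120, 80, by = 5),
                                         fs = 10000) {
  if (length(concentrations) == 0L)
    stop("concentration list must be non-empty")
  stopifnot(all(concentrations >= 0), ic50 > 0, slope_h != 0)
  set.seed(as.integer(seed))
  sched <- data.frame(
    level = NA_real_, onset = c(0, 0.010, 0.110, 0.130),
    duration = c(0.010, 0.100, 0.020, 0.020))
  n <- round(0.150 * fs)
  tt <- (seq_len(n) - 1L) / fs

  one_sweep <- function(v_test, na_factor) {
    sch <- sched
    sch$level <- c(-70, v_test, -10, -70)
    i <- numeric(n)
    in_test <- tt >= sch$onset[2] & tt < sch$onset[3]
    in_probe <- tt >= sch$onset[3] & tt < sch$onset[4]
    amp <- if (v_test > -60) exp(-((v_test + 35) / 20)^2) else 0
    i[in_test] <- i[in_test] -
      i_max * amp * na_factor * .nav_transient(tt[in_test] - sch$onset[2])
    if (v_test > -30) { # delayed-rectifier activation threshold
      gk <- 2 # pA/mV, Kv-like sustained conductance
      i[in_test] <- i[in_test] + gk * (v_test + 80) *
        (1 - exp(-(tt[in_test] - sch$onset[2]) / 0.005))
    }
    avail <- 1 / (1 + exp((v_test + 65) / 7))
    i[in_probe] <- i[in_probe] - 0.8 * i_max * avail * na_factor *
      .nav_transient(tt[in_probe] - sch$onset[3])
    if (noise_sd > 0) i <- i + stats::rnorm(n, 0, noise_sd)
    patch_sweep(tt, i, protocol = "voltage_step", step_schedule = sch)
  }

  family <- function(na_factor)
    lapply(potentials, one_sweep, na_factor = na_factor)
  conditions <- list(control = family(1))
  if (include_ttx) conditions$ttx <- family(0)
  for (conc in concentrations)
    conditions[[sprintf("c_%g", conc)]] <-
      family(1 - boltzmann_inhibition(conc, ic50, slope_h))
  list(potentials = potentials, conditions = conditions,
       truth = list(ic50 = ic50, slope_h = slope_h, i_max = i_max))
}

#' Simulate a current-clamp sweep with known action potentials
#'
#' Builds a membrane-voltage sweep of a given activity class from
#' Gaussian-shaped spikes on a flat resting potential plus Gaussian noise,
#' recording the analytic ground truth (spike times, peak voltages,
#' half-height width `2*sigma*sqrt(2*log(2))` and maximal slope
#' `height * exp(-1/2) / sigma`) as attribute `"truth"`.
#'
#' Kinds: `"quiet"` (no events), `"attempting"` (sub-0 mV spikes, 60 s),
#' `"spontaneous"` (overshooting spikes, 60 s), `"iap_single"` (one
#' overshooting spike, 1 s), `"iap_train"` (six overshooting spikes, 1 s),
#' `"iap_attempting"` (three sub-threshold humps, 1 s).
#'
#' @param kind Activity class to generate.
#' @param seed Integer seed.
#' @param fs Sampling rate, Hz (default 20000).
#' @param rest_mV Resting potential, mV.
#' @param noise_sd Voltage noise SD, mV (default 0.3).
#' @param sigma_ms Gaussian spike SD, ms (default 1; FWHM about 2.35 ms).
#' @return A gap-free [patch_sweep()] with attribute `"truth"`, a data
#'   frame of per-spike ground truth (empty for `"quiet"`).
#' @export
simulate_ap_sweep <- function(kind = c("quiet", "attempting", "spontaneous",
                                       "iap_single", "iap_train",
                                       "iap_attempting"),
                              seed = 1L, fs = 20000, rest_mV = -60,
                              noise_sd = 0.3, sigma_ms = 1) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  cfgk <- switch(kind,
    quiet          = list(dur = 60, times = numeric(0), height = 0),
    attempting     = list(dur = 60, times = seq(5, 55, length.out = 5),
                          height = -20 - rest_mV),
    spontaneous    = list(dur = 60, times = seq(5, 55, length.out = 5),
                          height = 25 - rest_mV),
    iap_single     = list(dur = 1, times = 0.5, height = 20 - rest_mV),
    iap_train      = list(dur = 1, times = seq(0.2, 0.8, length.out = 6),
                          height = 20 - rest_mV),
    iap_attempting = list(dur = 1, times = c(0.3, 0.65),
                          height = -35 - rest_mV))
  n <- round(cfgk$dur * fs)
  tt <- (seq_len(n) - 1L) / fs
  v <- rep(rest_mV, n)
  sig <- sigma_ms / 1000
  times <- if (length(cfgk$times) > 0L)
    cfgk$times + stats::runif(length(cfgk$times), -0.01, 0.01) else numeric(0)
  for (t0 in times) v <- v + cfgk$height * exp(-(tt - t0)^2 / (2 * sig^2))
  if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
  # closed-form expectations for a Gaussian bump: FWHM; the width measured
  # at half of (peak - threshold) when the threshold sits at the analytic
  # third-derivative peak of the rise (u = -sqrt(3 + sqrt(6)) sigma); and
  # the maximal slope height * exp(-1/2) / sigma.
  f_thr <- exp(-(3 + sqrt(6)) / 2)
  truth <- data.frame(
    time = times,
    peak_mV = rep(rest_mV + cfgk$height, length(times)),
    height = rep(cfgk$height, length(times)),
    sigma_ms = rep(sigma_ms, length(times)),
    fwhm_ms = rep(2 * sigma_ms * sqrt(2 * log(2)), length(times)),
    hhw_ms = rep(2 * sigma_ms * sqrt(2 * log(2 / (1 + f_thr))),
                 length(times)),
    max_dvdt = rep(cfgk$height * exp(-0.5) / sigma_ms, length(times)))
  sw <- patch_sweep(tt, v, protocol = if (cfgk$dur >= 30) "gapfree"
                                      else "current_step")
  attr(sw, "truth") <- truth
  sw
}
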