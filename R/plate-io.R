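#' Write a plate container to disk
#'
#' Serialises a simulated (or previously loaded) plate to a plain-text
#' directory container: `meta.json` (acquisition settings), `platemap.csv`
#' (well exposures), one wide CSV of voltage samples per phase
#' (`traces_<phase>.csv`, one column per channel), and, when present, the
#' ground-truth sidecars `truth.json` (compound truths, per-channel true
#' rates) and `true_spikes.csv`. Samples are written with 17 significant
#' digits so the round trip through [read_plate()] is bit-identical.
#'
#' @param plate A `simulated_plate` or the value of [read_plate()].
#' @param dir Directory to create/overwrite.
#' @return `dir`, invisibly.
#' @export
write_plate <- function(plate, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- plate$spec
  jsonlite::write_json(unclass(spec), file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(plate$exposures, file.path(dir, "platemap.csv"),
                   row.names = FALSE)
  phases <- names(plate$channels[[1]]$traces)
  chan_ids <- names(plate$channels)
  for (ph in phases) {
    cols <- lapply(plate$channels, function(ch)
      sprintf("%.17g", ch$traces[[ph]]$samples))
    lines <- do.call(paste, c(cols, sep = ","))
    con <- file(file.path(dir, sprintf("traces_%s.csv", ph)), "w")
    writeLines(c(paste(chan_ids, collapse = ","), lines), con)
    close(con)
  }
  if (!is.null(plate$truths)) {
    jsonlite::write_json(lapply(plate$truths, unclass),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    rates <- do.call(rbind, lapply(chan_ids, function(id) {
      ch <- plate$channels[[id]]
      data.frame(channel = id, well = ch$well, electrode = ch$electrode,
                 rate_baseline = ch$true_rates[["baseline"]],
                 rate_post = ch$true_rates[["post"]],
                 rate_washout = ch$true_rates[["washout"]])
    }))
    utils::write.csv(rates, file.path(dir, "true_rates.csv"),
                     row.names = FALSE)
    sp <- list()
    for (id in chan_ids) {
      for (ph in phases) {
        times <- plate$channels[[id]]$true_spikes[[ph]]
        if (length(times) > 0L)
          sp[[length(sp) + 1L]] <- data.frame(
            channel = id, phase = ph, time_s = sprintf("%.17g", times))
      }
    }
    utils::write.csv(do.call(rbind, sp), file.path(dir, "true_spikes.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a plate container from disk
#'
#' Inverse of [write_plate()]. Validates that every channel appears in
#' every phase; missing channels are reported in a structured error naming
#' the absent keys.
#'
#' @param dir Container directory.
#' @return A list shaped like a `simulated_plate` (class
#'   `"simulated_plate"`), with ground-truth fields present only when the
#'   sidecars exist.
#' @export
read_plate <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  spec <- do.call(plate_spec, meta)
  exposures <- utils::read.csv(file.path(dir, "platemap.csv"),
                               colClasses = c(well = "character"))
  trace_files <- list.files(dir, pattern = "^traces_.*\\.csv$")
  phases <- sub("^traces_(.*)\\.csv$", "\\1", trace_files)
  mats <- list(); headers <- list()
  for (i in seq_along(trace_files)) {
    f <- file.path(dir, trace_files[i])
    hdr <- strsplit(readLines(f, n = 1L), ",")[[1]]
    m <- utils::read.csv(f, colClasses = rep("numeric", length(hdr)),
                         check.names = FALSE)
    headers[[phases[i]]] <- hdr
    mats[[phases[i]]] <- m
  }
  all_ids <- sort(unique(unlist(headers)))
  missing <- list()
  for (ph in phases) {
    absent <- setdiff(all_ids, headers[[ph]])
    if (length(absent) > 0L) missing[[ph]] <- absent
  }
  if (length(missing) > 0L)
    stop("plate container is incomplete; missing channels: ",
         paste(sprintf("[%s] %s", names(missing),
                       vapply(missing, paste, "", collapse = ", ")),
               collapse = "; "))

  truths <- NULL; true_rates <- NULL; spikes <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    raw <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truths <- lapply(raw, function(x) do.call(compound_truth, x))
  }
  rf <- file.path(dir, "true_rates.csv")
  if (file.exists(rf)) true_rates <- utils::read.csv(rf)
  sf <- file.path(dir, "true_spikes.csv")
  if (file.exists(sf)) spikes <- utils::read.csv(sf)

  channels <- list()
  for (id in all_ids) {
    parts <- strsplit(id, "_")[[1]]
    ch <- list(well = parts[1], electrode = parts[2])
    ch$traces <- list()
    ch$true_spikes <- list()
    for (ph in phases) {
      ch$traces[[ph]] <- channel_trace(mats[[ph]][[id]], spec$sampling_rate,
                                       well_id = parts[1],
                                       electrode_id = parts[2], phase = ph)
      if (!is.null(spikes)) {
        sel <- spikes$channel == id & spikes$phase == ph
        ch$true_spikes[[ph]] <- as.numeric(spikes$time_s[sel])
      }
    }
    if (!is.null(true_rates)) {
      row <- true_rates[true_rates$channel == id, ]
      ch$baseline_rate <- row$rate_baseline
      ch$true_rates <- c(baseline = row$rate_baseline,
                         post = row$rate_post, washout = row$rate_washout)
    }
    channels[[id]] <- ch
  }
  structure(list(spec = spec, exposures = exposures, truths = truths,
                 channels = channels),
            class = "simulated_plate")
}

## half-up rounding to integers (2.5 -> 3), as used for printed percentages
.round_half_up <- function(x) floor(x + 0.5)

#' Tally activity classes with whole-percent shares
#'
#' Counts class labels (e.g. the gap-free or current-step patch-clamp
#' classes of a recorded cohort) and reports each class's share rounded
#' half-up to the nearest whole percent.
#'
#' @param labels Non-empty character vector of class labels.
#' @return An object of class `"class_tally"`: list with `counts` (named
#'   integer), `total`, and `percentages` (named, whole percent).
#' @export
#' @examples
#' tally_classes(rep(c("quiet", "attempting", "spontaneous"), c(29, 3, 11)))
tally_classes <- function(labels) {
  if (length(labels) == 0L) stop("cannot tally an empty label list")
  counts <- table(labels)
  total <- sum(counts)
  structure(list(counts = stats::setNames(as.integer(counts),
                                          names(counts)),
                 total = total,
                 percentages = stats::setNames(
                   .round_half_up(100 * as.integer(counts) / total),
                   names(counts))),
            class = "class_tally")
}

#' @export
print.class_tally <- function(x, ...) {
  cat(sprintf("Class tally (n = %d):\n", x$total))
  for (nm in names(x$counts))
    cat(sprintf("  %-18s %3d / %d  (%d%%)\n", nm, x$counts[[nm]], x$total,
                x$percentages[[nm]]))
  invisible(x)
}

#' Run the full screening funnel on a plate
#'
#' Executes the complete analysis chain on one plate: spike detection and
#' per-channel rates; per-compound screen statistics with library-wide FDR
#' correction and composite hit calling; LDH cytotoxicity verdicts; washout
#' reversibility and percent recovery; tier-matched Hill concentration-
#' response fits for the surviving compounds; and the final patch-clamp
#' candidate selection (IC50 <= 8 uM, recovery >= 60%). Stage-by-stage
#' counts are returned and funnel monotonicity (candidates, a subset of
#' reversible, of non-toxic, of hits) is asserted on every run.
#'
#' @param plate A `simulated_plate` (from [simulate_plate()] or
#'   [read_plate()]).
#' @param ldh LDH absorbance table; when `NULL` and the plate carries
#'   ground truth, one is simulated from it with `seed`.
#' @param dose_points Optional data frame (`compound_id`, `concentration`,
#'   `response`, `replicate`) of measured concentration-response points;
#'   when `NULL` and ground truth is available, per-compound points are
#'   simulated on the tier-matched concentration grid.
#' @param thresholds A [hit_thresholds()].
#' @param cfg A [detector_config()].
#' @param fig3_mode Enable the optional median-separation hit criterion.
#' @param seed Integer seed for any simulated assay stages.
#' @return An object of class `"screen_funnel"`: list with `rates`,
#'   `screen` (per-compound metrics + calls), `toxic`, `recovery`, `fits`,
#'   `candidates` and the stage `funnel` counts.
#' @export
run_pipeline <- function(plate, ldh = NULL, dose_points = NULL,
                         thresholds = hit_thresholds(),
                         cfg = detector_config(), fig3_mode = FALSE,
                         seed = 1L) {
  rates <- plate_rates(plate, cfg)
  screen <- screen_library(rates, plate$exposures, thresholds, cfg,
                           fig3_mode)
  hits <- screen$compound_id[screen$is_hit]

  if (is.null(ldh)) {
    if (is.null(plate$truths))
      stop("stage toxicity: no LDH table supplied and no ground truth ",
           "available to simulate one")
    ldh <- simulate_ldh(plate$truths, seed = seed)
  }
  toxic <- ldh_verdicts(ldh)
  nontoxic_hits <- hits[!toxic[hits]]

  # washout recovery per compound, from baseline-active channels
  recs <- list()
  for (cmpd in screen$compound_id) {
    wells <- plate$exposures$well[plate$exposures$compound_id == cmpd]
    sub <- rates[rates$well %in% wells, ]
    b <- sub[sub$phase == "baseline", ]
    key <- paste(b$well, b$electrode)
    a <- sub[sub$phase == "post", ]
    w <- sub[sub$phase == "washout", ]
    a <- a[match(key, paste(a$well, a$electrode)), ]
    w <- w[match(key, paste(w$well, w$electrode)), ]
    act <- classify_active(b$rate_hz, cfg)
    if (sum(act) < 1L || mean(b$rate_hz[act]) <= 0) next
    mb <- mean(b$rate_hz[act])
    rec <- list(compound_id = cmpd, activity_baseline = 100,
                activity_post = min(100, 100 * mean(a$rate_hz[act]) / mb),
                activity_washout = 100 * mean(w$rate_hz[act]) / mb)
    recs[[cmpd]] <- suppressWarnings(classify_reversibility(rec))
  }
  reversible <- nontoxic_hits[vapply(nontoxic_hits, function(cmpd)
    isTRUE(recs[[cmpd]]$reversible), logical(1))]

  fits <- list()
  for (cmpd in reversible) {
    tier <- screen$tier[screen$compound_id == cmpd]
    pts <- NULL
    if (!is.null(dose_points)) {
      pts <- dose_points[dose_points$compound_id == cmpd, ]
      if (nrow(pts) == 0L) pts <- NULL
    }
    if (is.null(pts)) {
      if (is.null(plate$truths)) next
      grid <- select_tier_range(tier)$concentrations
      pts <- simulate_dose_response_points(
        plate$truths[[cmpd]], grid,
        seed = seed + match(cmpd, screen$compound_id))
    }
    fits[[cmpd]] <- fit_dose_response(pts, "hill_log")
  }
  candidates <- select_patch_candidates(fits, recs, toxic)

  funnel <- c(screened = nrow(screen), hits = length(hits),
              non_toxic = length(nontoxic_hits),
              reversible = length(reversible),
              fitted = sum(vapply(fits, function(f) isTRUE(f$converged),
                                  logical(1))),
              candidates = length(candidates))
  stopifnot(all(candidates %in% reversible),
            all(reversible %in% nontoxic_hits),
            all(nontoxic_hits %in% hits))
  structure(list(rates = rates, screen = screen, toxic = toxic,
                 recovery = recs, fits = fits, candidates = candidates,
                 funnel = funnel),
            class = "screen_funnel")
}

#' @export
print.screen_funnel <- function(x, ...) {
  cat("Screening funnel:\n")
  lbl <- c(screened = "compounds screened", hits = "composite hits",
           non_toxic = "non-toxic hits", reversible = "reversible",
           fitted = "converged CR fits",
           candidates = "patch-clamp candidates")
  for (nm in names(x$funnel))
    cat(sprintf("  %-24s %d\n", lbl[[nm]], x$funnel[[nm]]))
  if (length(x$candidates) > 0L)
    cat("  candidates:", paste(x$candidates, collapse = ", "), "\n")
  invisible(x)
}
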