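#' LDH cytotoxicity activity, % of positive control
#'
#' Background-subtracted LDH activity normalised between the vehicle and
#' lysis (positive) controls: each reading is reduced to `a490 - a680`
#' (LDH absorbance minus background), and the sample is expressed as
#' `100 * (sample - vehicle) / (positive - vehicle)`.
#'
#' @param reading,vehicle,positive Lists or one-row data frames with fields
#'   `a490` and `a680` (absorbance units, >= 0).
#' @return LDH activity as a percentage of the positive control.
#' @export
ldh_activity <- function(reading, vehicle, positive) {
  delta <- function(x) {
    stopifnot(x$a490 >= 0, x$a680 >= 0)
    x$a490 - x$a680
  }
  s <- delta(reading); v <- delta(vehicle); p <- delta(positive)
  if (p <= v)
    stop("assay failure: positive control does not exceed vehicle control")
  100 * (s - v) / (p - v)
}

#' Cytotoxicity verdict from LDH activity
#'
#' A compound is cytotoxic when its LDH activity exceeds 5% of the positive
#' control at any measured timepoint (worst case over the 1, 6 and 24 h
#' reads).
#'
#' @param activity_pct LDH activity value(s), % of positive control; one per
#'   timepoint.
#' @param threshold Toxicity threshold, % (default 5).
#' @return Logical flag.
#' @export
is_cytotoxic <- function(activity_pct, threshold = 5) {
  stopifnot(length(activity_pct) > 0L)
  any(activity_pct > threshold)
}

#' Classify washout reversibility and compute percent recovery
#'
#' Reversibility is an increase of neuronal activity following washout.
#' Recovery is the fraction of the inhibited gap regained:
#' `100 * (washout - post) / (baseline - post)`, clipped to `[0, 100]`.
#'
#' @param rec A list with fields `compound_id`, `activity_baseline`
#'   (typically 100, the pre-compound reference), `activity_post` and
#'   `activity_washout` (both % of baseline).
#' @param min_increase Minimum washout-minus-post increase (% of baseline)
#'   required to call the change real rather than measurement noise; 0 keeps
#'   the strict-increase reading.
#' @param denominator `"gap"` (default; fraction of the inhibited gap
#'   regained) or `"baseline"` (washout activity relative to baseline).
#' @return `rec` augmented with `reversible`, `recovery_pct` and a logical
#'   `undefined` flag (set when the compound produced no inhibition, in
#'   which case recovery is meaningless).
#' @export
classify_reversibility <- function(rec, min_increase = 0,
                                   denominator = c("gap", "baseline")) {
  denominator <- match.arg(denominator)
  stopifnot(rec$activity_post <= rec$activity_baseline)
  if (rec$activity_post >= rec$activity_baseline) {
    rec$reversible <- NA
    rec$recovery_pct <- NA_real_
    rec$undefined <- TRUE
    warning(sprintf("compound %s produced no inhibition; recovery undefined",
                    rec$compound_id))
    return(rec)
  }
  gain <- rec$activity_washout - rec$activity_post
  rec$reversible <- gain > min_increase
  raw <- switch(denominator,
    gap = 100 * gain / (rec$activity_baseline - rec$activity_post),
    baseline = 100 * rec$activity_washout / rec$activity_baseline)
  rec$recovery_pct <- min(100, max(0, raw))
  rec$undefined <- FALSE
  rec
}

#' Per-compound cytotoxicity verdicts from an LDH absorbance table
#'
#' Computes [ldh_activity()] for every sample reading against the vehicle
#' and positive controls of the same timepoint and aggregates the verdict
#' over timepoints by worst case ([is_cytotoxic()]).
#'
#' @param ldh A table as returned by [simulate_ldh()]: columns
#'   `compound_id`, `role`, `timepoint_h`, `a490`, `a680`.
#' @param threshold Toxicity threshold, % of positive control (default 5).
#' @return Named logical vector, one verdict per compound.
#' @export
ldh_verdicts <- function(ldh, threshold = 5) {
  stopifnot(all(c("compound_id", "role", "timepoint_h", "a490", "a680") %in%
                names(ldh)))
  compounds <- unique(ldh$compound_id[ldh$role == "sample"])
  out <- stats::setNames(logical(length(compounds)), compounds)
  for (cmpd in compounds) {
    acts <- numeric(0)
    for (tp in unique(ldh$timepoint_h)) {
      at <- function(role, id = NULL) {
        sel <- ldh$role == role & ldh$timepoint_h == tp
        if (!is.null(id)) sel <- sel & ldh$compound_id == id
        ldh[which(sel)[1], c("a490", "a680")]
      }
      acts <- c(acts, ldh_activity(at("sample", cmpd), at("vehicle"),
                                   at("positive_control")))
    }
    out[cmpd] <- is_cytotoxic(acts, threshold)
  }
  out
}

#' Select patch-clamp candidates from the screen funnel
#'
#' Final funnel stage: keeps compounds whose converged concentration-response
#' fit gives IC50 <= 8 uM, whose washout recovery is >= 60% with a
#' reversible classification, and which are non-cytotoxic.
#'
#' @param fits Named list of [fit_dose_response()] objects (names are
#'   compound ids).
#' @param recs Named list of records from [classify_reversibility()].
#' @param toxic Named logical vector of [is_cytotoxic()] verdicts.
#' @param ic50_max IC50 cut, uM (default 8).
#' @param recovery_min Recovery cut, % (default 60).
#' @return Character vector of selected compound ids.
#' @export
select_patch_candidates <- function(fits, recs, toxic,
                                    ic50_max = 8, recovery_min = 60) {
  out <- character(0)
  for (cmpd in names(fits)) {
    f <- fits[[cmpd]]; r <- recs[[cmpd]]
    if (is.null(r) || is.na(toxic[cmpd])) next
    if (isTRUE(f$converged) && f$ic50 <= ic50_max &&
        isTRUE(r$reversible) && !isTRUE(r$undefined) &&
        r$recovery_pct >= recovery_min && !toxic[cmpd])
      out <- c(out, cmpd)
  }
  out
}
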