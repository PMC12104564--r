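#' Inhibitory Hill activity model
#'
#' Two-parameter inhibitory Hill curve on the normalised-activity scale used
#' for MEA concentration-response data: asymptotes are fixed at 100% activity
#' (vehicle) and 0% (complete suppression), so the only free parameters are
#' the half-maximal inhibitory concentration and the Hill coefficient.
#'
#' @param conc Concentration(s), uM. Must be non-negative.
#' @param ic50 Half-maximal inhibitory concentration, uM (> 0).
#' @param n Hill coefficient (dimensionless, > 0); steepness of the curve.
#'
#' @return Remaining activity as a percentage of baseline: `100 / (1 +
#'   (conc/ic50)^n)`. At `conc = 0` this is exactly 100; at `conc = ic50`
#'   exactly 50 (i.e. 50% inhibition).
#' @seealso [boltzmann_inhibition()], [fit_dose_response()]
#' @export
#' @examples
#' hill_activity(c(0, 4, 40), ic50 = 4, n = 3.2)
hill_activity <- function(conc, ic50, n) {
  stopifnot(is.numeric(conc), all(conc >= 0), ic50 > 0, n > 0)
  100 / (1 + (conc / ic50)^n)
}

#' Boltzmann inhibition model in linear concentration
#'
#' Sigmoid block model used for patch-clamp concentration-response data where
#' the response is the TTX-normalised inhibition fraction `dI/dI_TTX`. The
#' slope factor `h` carries concentration units (uM), i.e. the sigmoid lives
#' on the linear concentration axis rather than on log-concentration.
#'
#' @param conc Concentration(s), uM.
#' @param ic50 Midpoint concentration, uM.
#' @param h Slope factor, uM; must be non-zero. Positive `h` gives an
#'   inhibition fraction that increases with concentration.
#'
#' @return Inhibition fraction `1 / (1 + exp((ic50 - conc)/h))`; exactly 0.5
#'   at `conc = ic50`.
#' @export
#' @examples
#' boltzmann_inhibition(4, ic50 = 4, h = 3.2)      # 0.5
#' boltzmann_inhibition(4 + 3.2, ic50 = 4, h = 3.2) # 1/(1 + exp(-1))
boltzmann_inhibition <- function(conc, ic50, h) {
  stopifnot(is.numeric(conc), h != 0)
  1 / (1 + exp((ic50 - conc) / h))
}

#' Tiered concentration ranges for follow-up dose-response runs
#'
#' Returns the fixed concentration grid assigned to each hit-intensity tier;
#' 0 uM is the DMSO vehicle point.
#'
#' @param tier One of `"high"`, `"moderate"`, `"low"`.
#' @return A list with elements `tier` and `concentrations` (uM, decreasing,
#'   ending in the vehicle 0).
#' @export
#' @examples
#' select_tier_range("high")$concentrations
select_tier_range <- function(tier) {
  tier <- match.arg(tier, c("high", "moderate", "low"))
  grids <- list(
    high     = c(10, 8, 6, 4, 2, 0),
    moderate = c(12.5, 10, 7.5, 5, 2.5, 0),
    low      = c(16.6, 13.3, 10, 6.6, 3.3, 0)
  )
  list(tier = tier, concentrations = sort(grids[[tier]], decreasing = TRUE))
}

## model-specific response functions on the optimiser's log-parameter scale
.dr_response <- function(model, conc, ic50, slope) {
  switch(model,
    hill_log         = hill_activity(conc, ic50, slope),
    boltzmann_linear = boltzmann_inhibition(conc, ic50, slope)
  )
}

#' Fit a concentration-response model by nonlinear least squares
#'
#' Fits either the inhibitory Hill model ([hill_activity()], responses on the
#' % activity scale) or the linear-concentration Boltzmann block model
#' ([boltzmann_inhibition()], responses on the inhibition-fraction scale) by
#' minimising the sum of squared residuals. Optimisation is multi-start:
#' IC50 is started on a log-spaced grid spanning the observed concentration
#' range (at least 5 starts) and the fit with lowest SSE wins, ties broken by
#' the smaller IC50. Parameters are optimised on the log scale, which
#' enforces the positivity constraints without explicit bounds.
#'
#' A fit is flagged as showing no concentration-effect relationship
#' (`converged = FALSE`, `flag = "no dose dependence"`) when the model
#' reduces the SSE of the constant-mean model by less than 1%, the situation
#' seen for compounds whose activity does not change across the tested range.
#'
#' @param points A data frame with columns `concentration` (uM, >= 0) and
#'   `response` (% activity for `hill_log`, inhibition fraction for
#'   `boltzmann_linear`). A `replicate` column is allowed and ignored by the
#'   fitter; replicate points enter the SSE individually.
#' @param model `"hill_log"` or `"boltzmann_linear"`.
#' @param init Optional named vector `c(ic50 = , slope = )` added to the
#'   start grid.
#' @param n_starts Number of log-spaced IC50 starting values (>= 5).
#'
#' @return An object of class `"dose_response_fit"`: a list with components
#'   `model`, `ic50`, `slope` (Hill n, or Boltzmann slope factor in uM),
#'   `r_squared`, `sse`, `converged`, `flag`, `data`, `fitted` and
#'   `concentration_grid`. Supports `print()`, `summary()`, `coef()`,
#'   `predict()`, `fitted()`, `residuals()` and `plot()`.
#' @export
#' @examples
#' grid <- select_tier_range("high")$concentrations
#' pts <- data.frame(concentration = grid,
#'                   response = hill_activity(grid, ic50 = 4, n = 3.2))
#' fit <- fit_dose_response(pts, "hill_log")
#' coef(fit)
fit_dose_response <- function(points, model = c("hill_log", "boltzmann_linear"),
                              init = NULL, n_starts = 7L) {
  model <- match.arg(model)
  stopifnot(is.data.frame(points),
            all(c("concentration", "response") %in% names(points)))
  conc <- as.numeric(points$concentration)
  resp <- as.numeric(points$response)
  ok <- is.finite(conc) & is.finite(resp)
  conc <- conc[ok]; resp <- resp[ok]
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (length(unique(conc)) < 4L)
    stop("need responses at >= 4 distinct concentrations")
  n_starts <- max(5L, as.integer(n_starts))

  sse_fun <- function(par) {
    pred <- .dr_response(model, conc, exp(par[1]), exp(par[2]))
    sum((resp - pred)^2)
  }

  pos <- conc[conc > 0]
  lo <- min(pos); hi <- max(pos)
  ic50_starts <- exp(seq(log(lo / 3), log(hi * 3), length.out = n_starts))
  slope_starts <- switch(model,
    hill_log         = c(1, 3),
    boltzmann_linear = c((hi - lo) / 4, (hi - lo)) # slope factor ~ conc scale
  )
  starts <- expand.grid(ic50 = ic50_starts, slope = slope_starts)
  if (!is.null(init)) {
    stopifnot(all(c("ic50", "slope") %in% names(init)), init["ic50"] > 0,
              init["slope"] > 0)
    starts <- rbind(starts, data.frame(ic50 = init[["ic50"]],
                                       slope = init[["slope"]]))
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(log(as.numeric(starts[i, ])), sse_fun,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
    take <- is.null(best) ||
      fit$value < best$value * (1 - 1e-10) ||
      (abs(fit$value - best$value) <= best$value * 1e-10 + 1e-300 &&
       fit$par[1] < best$par[1])
    if (take) best <- fit
  }

  ic50 <- exp(best$par[1]); slope <- exp(best$par[2])
  sse <- best$value
  sst <- sum((resp - mean(resp))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  no_dep <- sst == 0 || (sst - sse) / sst < 0.01
  structure(list(
    model = model, ic50 = ic50, slope = slope,
    r_squared = r2, sse = sse,
    converged = best$convergence == 0 && !no_dep,
    flag = if (no_dep) "no dose dependence" else NA_character_,
    data = data.frame(concentration = conc, response = resp),
    fitted = .dr_response(model, conc, ic50, slope),
    concentration_grid = sort(unique(conc))
  ), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, digits = 4, ...) {
  lbl <- c(hill_log = "inhibitory Hill (log-concentration)",
           boltzmann_linear = "Boltzmann block (linear concentration)")[x$model]
  cat("Concentration-response fit:", lbl, "\n")
  if (!is.na(x$flag)) cat("  ** flagged:", x$flag, "**\n")
  su <- if (x$model == "hill_log") "" else " uM"
  cat(sprintf("  IC50  = %.*g uM\n", digits, x$ic50))
  cat(sprintf("  slope = %.*g%s\n", digits, x$slope, su))
  cat(sprintf("  R^2   = %.*g   (SSE %.*g, %d points)\n",
              digits, x$r_squared, digits, x$sse, nrow(x$data)))
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(ic50 = object$ic50, slope = object$slope)
}

#' @export
fitted.dose_response_fit <- function(object, ...) object$fitted

#' @export
residuals.dose_response_fit <- function(object, ...) {
  object$data$response - object$fitted
}

#' Predict from a fitted concentration-response model
#'
#' @param object A `dose_response_fit`.
#' @param newdata Optional data frame with a `concentration` column (or a
#'   bare numeric vector of concentrations). Defaults to the fitted points.
#' @param ... Unused.
#' @return Predicted responses on the model's response scale.
#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration
          else if (is.numeric(newdata)) newdata
          else newdata$concentration
  .dr_response(object$model, conc, object$ic50, object$slope)
}

#' @export
summary.dose_response_fit <- function(object, ...) {
  out <- object
  out$residual_sd <- sqrt(object$sse / max(1L, nrow(object$data) - 2L))
  class(out) <- c("summary.dose_response_fit", class(object))
  out
}

#' @export
print.summary.dose_response_fit <- function(x, digits = 4, ...) {
  NextMethod()
  cat(sprintf("  residual SD = %.*g\n", digits, x$residual_sd))
  rq <- stats::quantile(x$data$response - x$fitted)
  cat("  residual quartiles:",
      paste(signif(rq, 3), collapse = "  "), "\n")
  invisible(x)
}

#' Plot a concentration-response fit
#'
#' Draws the observed points and the fitted curve on a log-concentration
#' axis; the vehicle (0 uM) point is placed half a decade below the lowest
#' tested concentration.
#'
#' @param x A `dose_response_fit`.
#' @param n_curve Number of points on the drawn curve.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dose_response_fit <- function(x, n_curve = 200, ...) {
  conc <- x$data$concentration
  pos <- conc[conc > 0]
  x0 <- min(pos) / sqrt(10) # pseudo-position for the vehicle point
  px <- ifelse(conc > 0, conc, x0)
  cg <- exp(seq(log(x0), log(max(pos)), length.out = n_curve))
  ylab <- if (x$model == "hill_log") "activity (% baseline)"
          else "inhibition fraction (dI/dI_TTX)"
  graphics::plot(px, x$data$response, log = "x",
                 xlab = "concentration (uM)", ylab = ylab, ...)
  graphics::lines(cg, predict(x, cg))
  graphics::abline(v = x$ic50, lty = 3)
  invisible(x)
}
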