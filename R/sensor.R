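#' Sensor parameter presets
#'
#' Two shipped sensor configurations: \code{"reference"} (\code{Ki_I = 0.3},
#' \code{k_GFP = 0.1}/min) used for the dose-response and nutrient-upshift
#' analyses, and \code{"diagnostic"} (\code{Ki_I = 0.1}, the optimal
#' inhibition strength) used for producer-line diagnostics, where a steeper
#' GFP-vs-Tes dependence is wanted.
#'
#' @param name \code{"reference"} or \code{"diagnostic"}.
#' @param params Base parameter set to modify.
#' @return A \code{ppgpp_parameters} object.
#' @export
sensor_preset <- function(name = c("reference", "diagnostic"),
                          params = model_parameters()) {
  name <- match.arg(name)
  p <- unclass(params)
  p$Ki_I <- switch(name, reference = 0.3, diagnostic = 0.1)
  p$k_GFP <- 0.1
  validate_parameters(p)
  structure(p, class = "ppgpp_parameters")
}

#' Steady state of the sensor cascade at clamped ppGpp
#'
#' At a fixed ppGpp concentration the repressor relay settles to the closed
#' form \eqn{I^* = P1P2(ppGpp)} and
#' \eqn{GFP^* = 1/(1 + (I^*/Ki_I)^l)}. Vectorised over \code{ppGpp}.
#'
#' @param ppGpp Clamped ppGpp concentration(s), uM.
#' @param p A \code{ppgpp_parameters} object.
#' @return A data frame with columns \code{ppGpp}, \code{I}, \code{GFP}.
#' @seealso \code{\link{dose_response_curve}}
#' @export
sensor_steady_state <- function(ppGpp, p) {
  if (any(ppGpp < 0)) stop("negative ppGpp")
  I <- p1p2_activity(ppGpp, p)
  GFP <- 1 / (1 + (I / p$Ki_I)^p$l_hill)
  data.frame(ppGpp = ppGpp, I = I, GFP = GFP)
}

#' Steady-state GFP dose-response to ppGpp
#'
#' Evaluates the sensor's steady-state transfer curve over a ppGpp grid.
#' The double-negative relay (ppGpp dashes P1/P2 dashes I dashes GFP)
#' composes into a monotone increasing map from ppGpp to GFP, which is what
#' makes GFP a faithful reporter of ppGpp over the observable 50--1000 uM
#' range.
#'
#' @param ppGpp_grid Increasing non-negative ppGpp grid, uM. The default
#'   spans the observable range.
#' @param p A \code{ppgpp_parameters} object.
#' @return A data frame (\code{ppGpp}, \code{I}, \code{GFP}), one row per
#'   grid point.
#' @export
dose_response_curve <- function(ppGpp_grid = 10^seq(log10(10), log10(2000),
                                                    length.out = 40),
                                p = sensor_preset("reference")) {
  if (is.unsorted(ppGpp_grid, strictly = FALSE))
    stop("ppGpp_grid must be increasing")
  sensor_steady_state(ppGpp_grid, p)
}

#' Biosensor response time after a nutrient upshift
#'
#' Simulates batch growth with a nutrient upshift anchored at the end of
#' the exponential phase (applied once the stringent response has
#' developed; see \code{\link{simulate_with_upshift}}) and returns
#' T0.5,GFP: the time needed for a 2-fold decrease of GFP fluorescence
#' after the upshift, linearly interpolated between output points.
#'
#' T0.5,GFP shortens with faster GFP turnover (\code{k_GFP}) and with
#' stronger repression of GFP expression (smaller \code{Ki_I}): the decay
#' has two stages, the repressor I climbing back past \code{Ki_I} (which
#' shuts GFP production off) followed by first-order GFP decay at
#' \code{k_GFP}. In the limit of fully repressed production T0.5,GFP
#' approaches \code{log(2)/k_GFP}.
#'
#' @param params A \code{ppgpp_parameters} object.
#' @param threshold Upshift trigger level on \code{lim}.
#' @param value Restored \code{lim} level.
#' @param delay Minutes between the \code{lim} crossing and the upshift.
#' @param t_end,output_dt Horizon and output spacing, min.
#' @return T0.5,GFP in minutes, with attributes \code{t_event} and
#'   \code{GFP_event} (the upshift time and the GFP level then).
#' @examples
#' \donttest{
#' t05 <- response_time(sensor_preset("reference"))
#' }
#' @export
response_time <- function(params, threshold = 0.01, value = 1, delay = 60,
                          t_end = 1440, output_dt = 1) {
  traj <- simulate_with_upshift(params, threshold = threshold, value = value,
                                delay = delay, t_end = t_end,
                                output_dt = output_dt)
  ev <- traj$events_applied
  t_ev <- ev$time[ev$action == "set_lim"][1]
  gfp_ev <- traj_interp(traj, "GFP", t_ev)
  if (gfp_ev <= 0) stop("GFP is zero at the upshift; response time undefined")
  after <- traj$time >= t_ev
  t_half <- first_crossing(traj$time[after], traj$state[after, "GFP"],
                           gfp_ev / 2)
  if (is.na(t_half))
    stop(errorCondition(
      paste0("GFP did not halve within the horizon (t_end = ", t_end,
             " min) after the upshift at t = ", round(t_ev, 2)),
      class = c("ppgpp_half_decay_not_reached", "error", "condition")))
  structure(t_half - t_ev, t_event = t_ev, GFP_event = gfp_ev)
}

#' Peak GFP fluorescence of a trajectory
#'
#' Global maximum of GFP along a trajectory. Around an interior discrete
#' maximum the peak is refined by quadratic interpolation through the three
#' bracketing points, making the metric insensitive to the output grid.
#'
#' @param traj A \code{ppgpp_trajectory}.
#' @return A list with \code{GFP_peak} and \code{t_GFP_peak} (min).
#' @export
peak_gfp <- function(traj) {
  stopifnot(inherits(traj, "ppgpp_trajectory"))
  pk <- quad_peak(traj$time, traj$state[, "GFP"])
  list(GFP_peak = pk$value, t_GFP_peak = pk$t)
}

## Grid-independent maximum: quadratic interpolation through the three
## points bracketing the discrete maximum (falls back to the grid point at
## the boundary or on degenerate curvature).
quad_peak <- function(t, v) {
  i <- which.max(v)
  if (i == 1 || i == length(v)) return(list(t = t[i], value = v[i]))
  tt <- t[(i - 1):(i + 1)]; vv <- v[(i - 1):(i + 1)]
  fit <- stats::lm.fit(cbind(1, tt - tt[2], (tt - tt[2])^2), vv)
  b <- fit$coefficients
  if (!is.finite(b[3]) || b[3] >= 0) return(list(t = t[i], value = v[i]))
  dt <- -b[2] / (2 * b[3])
  dt <- max(min(dt, tt[3] - tt[2]), tt[1] - tt[2])
  list(t = unname(tt[2] + dt),
       value = unname(b[1] + b[2] * dt + b[3] * dt^2))
}

#' Sensor metrics for a scenario
#'
#' Bundles the biosensor characteristics of one simulated scenario: the
#' response time after a nutrient upshift (if requested), the peak GFP level
#' and its time, and the steady-state dose-response of the configured
#' sensor.
#'
#' @param params A \code{ppgpp_parameters} object.
#' @param traj Optional pre-computed batch trajectory for the peak metrics;
#'   simulated if missing.
#' @param with_response_time Also compute T0.5,GFP (one extra simulation).
#' @return A list of class \code{ppgpp_sensor_metrics}.
#' @export
sensor_metrics <- function(params, traj = NULL, with_response_time = FALSE) {
  if (is.null(traj)) traj <- simulate_scenario(scenario(params))
  pk <- peak_gfp(traj)
  out <- list(GFP_peak = pk$GFP_peak, t_GFP_peak = pk$t_GFP_peak,
              T05_GFP = if (with_response_time)
                as.numeric(response_time(params)) else NA_real_,
              dose_response = dose_response_curve(p = params))
  class(out) <- "ppgpp_sensor_metrics"
  out
}

#' @export
print.ppgpp_sensor_metrics <- function(x, ...) {
  cat(sprintf("GFP peak %.3g at t = %.1f min", x$GFP_peak, x$t_GFP_peak))
  if (!is.na(x$T05_GFP)) cat(sprintf("; T0.5,GFP = %.1f min", x$T05_GFP))
  cat("\n")
  invisible(x)
}
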