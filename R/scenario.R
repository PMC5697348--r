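#' Scenario events
#'
#' Events modify the simulation at a fixed time (\code{event_at}) or when a
#' state variable first crosses a threshold from above (\code{event_when}).
#' Supported actions: \code{"set_lim"} and \code{"set_nutr"} reset a nutrient
#' pool (e.g. a nutrient upshift restores \code{lim} to 1),
#' \code{"clamp_ppGpp"} fixes ppGpp at a value until \code{"release_clamp"}.
#' All other state variables are continuous across an event; integration is
#' restarted at the event time.
#'
#' @param time Event time, min.
#' @param action One of \code{"set_lim"}, \code{"set_nutr"},
#'   \code{"clamp_ppGpp"}, \code{"release_clamp"}.
#' @param value Action value (ignored for \code{"release_clamp"}).
#' @return An object of class \code{ppgpp_event}.
#' @examples
#' ev <- event_when("lim", 0.01, "set_lim", 1)  # nutrient upshift
#' @export
event_at <- function(time, action, value = NULL) {
  new_event(time = time, trigger_var = NULL, threshold = NULL,
            action = action, value = value)
}

#' @rdname event_at
#' @param trigger_var State variable watched for a downward crossing
#'   (\code{"lim"}, \code{"nutr"}, or any state name).
#' @param threshold Crossing threshold (the event fires the first time
#'   \code{trigger_var} falls to this value).
#' @param delay Minutes between the trigger crossing and the action being
#'   applied (default 0: applied at the crossing). A delayed trigger lets a
#'   perturbation be anchored to a phase transition but applied once the
#'   downstream response has developed.
#' @export
event_when <- function(trigger_var, threshold, action, value = NULL,
                       delay = 0) {
  if (!is.numeric(delay) || delay < 0) stop("delay must be >= 0")
  new_event(time = NULL, trigger_var = trigger_var, threshold = threshold,
            action = action, value = value, delay = delay)
}

new_event <- function(time, trigger_var, threshold, action, value,
                      delay = 0) {
  actions <- c("set_lim", "set_nutr", "clamp_ppGpp", "release_clamp")
  if (!action %in% actions)
    stop("unknown event action '", action, "'; must be one of: ",
         paste(actions, collapse = ", "))
  if (action != "release_clamp") {
    if (is.null(value) || !is.numeric(value) || value < 0)
      stop("event action '", action, "' needs a non-negative value")
  }
  if (!is.null(trigger_var)) {
    if (!trigger_var %in% state_names())
      stop("unknown trigger variable '", trigger_var, "'")
    if (!is.numeric(threshold) || threshold <= 0)
      stop("trigger threshold must be positive")
  } else {
    if (!is.numeric(time) || time < 0) stop("event time must be >= 0")
  }
  structure(list(time = time, trigger_var = trigger_var,
                 threshold = threshold, action = action, value = value,
                 delay = delay),
            class = "ppgpp_event")
}

#' Define a simulation scenario
#'
#' A scenario bundles a parameter set, initial conditions, a horizon, an
#' output grid and an event schedule. The default initial condition
#' \code{"pre-equilibrate"} starts the culture in established exponential
#' growth (see \code{\link{pre_equilibrate}}), matching how batch-growth
#' trajectories are initialised throughout the package.
#'
#' @param params A \code{ppgpp_parameters} object.
#' @param init Either \code{"pre-equilibrate"} or a \code{\link{model_state}}.
#' @param t_end Simulation horizon, min. Default 1440 (24 h, the yield
#'   horizon).
#' @param output_dt Output grid spacing, min.
#' @param events List of \code{\link{event_at}} / \code{\link{event_when}}
#'   objects.
#' @return An object of class \code{ppgpp_scenario}.
#' @seealso \code{\link{simulate_scenario}}
#' @export
scenario <- function(params = model_parameters(), init = "pre-equilibrate",
                     t_end = 1440, output_dt = 5, events = list()) {
  stopifnot(inherits(params, "ppgpp_parameters"))
  if (!identical(init, "pre-equilibrate")) {
    init <- validate_state(init)
  }
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0")
  if (!is.numeric(output_dt) || output_dt <= 0) stop("output_dt must be > 0")
  if (inherits(events, "ppgpp_event")) events <- list(events)
  for (ev in events) {
    if (!inherits(ev, "ppgpp_event")) stop("events must be ppgpp_event objects")
    if (!is.null(ev$time) && ev$time > t_end)
      stop("event time ", ev$time, " outside [0, t_end]")
  }
  structure(list(params = params, init = init, t_end = t_end,
                 output_dt = output_dt, events = events),
            class = "ppgpp_scenario")
}

#' Initial state in established exponential growth
#'
#' Computes initial conditions consistent with balanced exponential growth:
#' the intracellular variables (Acyl-ACP, ppGpp, rib, I, GFP) are relaxed to
#' their quasi-steady values with both nutrient pools clamped at 1 and the
#' cell number held fixed, then the culture is started at \code{N0} with
#' \code{FA = 0} and \code{nutr = lim = 1}. This avoids spurious transients
#' at the start of batch trajectories.
#'
#' @param params A \code{ppgpp_parameters} object.
#' @param N0 Starting cell number, OD600 units.
#' @param t_eq Relaxation horizon for the quasi-steady solve, min.
#' @param rtol,atol Integration tolerances for the relaxation.
#' @return A \code{ppgpp_state}.
#' @export
pre_equilibrate <- function(params, N0 = 0.01, t_eq = 5000,
                            rtol = 1e-10, atol = 1e-12) {
  p <- unclass(params)
  p$k_nutr <- 0; p$k_lim <- 0; p$K_gr <- 0  # clamp nutrients and cell number
  y0 <- c(AcylACP = 0.5, FA = 0, N = N0, nutr = 1, lim = 1,
          ppGpp = 50, rib = 0.9)
  out <- deSolve::ode(y0, c(0, t_eq), core_rhs, p,
                      method = "lsoda", rtol = rtol, atol = atol)
  y <- out[nrow(out), core_names()]
  y["FA"] <- 0; y["N"] <- N0; y["nutr"] <- 1; y["lim"] <- 1
  ## the sensor relay equilibrates to its closed form at the core fixed point
  I0 <- 1 / (1 + (y[["ppGpp"]] / p$Ki_P1P2_ppGpp)^p$m_hill)
  GFP0 <- 1 / (1 + (I0 / p$Ki_I)^p$l_hill)
  y <- c(y, I = I0, GFP = GFP0)[state_names()]
  y <- pmin(pmax(y, 0), c(Inf, Inf, Inf, 1, 1, Inf, Inf, 1, 1))
  structure(y, class = "ppgpp_state")
}
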