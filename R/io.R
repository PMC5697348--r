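## CSV column order is part of the export contract.
csv_columns <- function() {
  c("t_min", "acyl_acp_uM", "fa_mg_per_l", "n_od", "nutr", "lim", "ppgpp_uM",
    "rib", "i", "gfp", "v_fas", "v_pls", "v_fa", "p1p2", "v_g")
}

#' Export a trajectory to CSV
#'
#' Writes the trajectory (states plus derived rates) as CSV with a fixed
#' header and column order and 15 significant digits, period decimal
#' separator, locale-independent. If any events were applied they are
#' written to a JSON sidecar \code{<path>.events.json}.
#'
#' @param traj A \code{ppgpp_trajectory}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{read_trajectory_csv}}
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "ppgpp_trajectory"))
  if (!length(traj$time)) stop("empty trajectory; nothing written")
  df <- as.data.frame(traj)
  names(df) <- csv_columns()
  txt <- vapply(df, function(col) formatC(col, digits = 15, format = "g"),
                character(nrow(df)))
  if (nrow(df) == 1L) txt <- matrix(txt, nrow = 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(csv_columns(), collapse = ","), con)
  writeLines(apply(txt, 1, paste, collapse = ","), con)
  if (nrow(traj$events_applied))
    jsonlite::write_json(traj$events_applied,
                         paste0(path, ".events.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trajectory CSV written by \code{write_trajectory_csv}
#'
#' @param path CSV path.
#' @return A data frame with the exported columns.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), csv_columns()))
    stop("not a trajectory CSV (unexpected columns): ", path)
  df
}

#' Export sensor metrics to JSON
#'
#' One JSON record per scenario: preset name, parameter overrides relative
#' to the reference set, and the computed metrics.
#'
#' @param metrics A \code{ppgpp_sensor_metrics} object.
#' @param path Output JSON path.
#' @param preset Label for the sensor configuration.
#' @param params The parameter set the metrics were computed under (used to
#'   report overrides relative to the reference defaults).
#' @return \code{path}, invisibly.
#' @export
write_sensor_metrics_json <- function(metrics, path, preset = "reference",
                                      params = NULL) {
  stopifnot(inherits(metrics, "ppgpp_sensor_metrics"))
  overrides <- list()
  if (!is.null(params)) {
    ref <- unclass(model_parameters())
    for (k in setdiff(names(ref), "ACP_conserved"))
      if (!isTRUE(all.equal(params[[k]], ref[[k]])))
        overrides[[k]] <- params[[k]]
  }
  rec <- list(preset = preset, overrides = overrides,
              T05_GFP = metrics$T05_GFP, GFP_peak = metrics$GFP_peak,
              t_GFP_peak = metrics$t_GFP_peak)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Write a run manifest
#'
#' Captures everything needed to reproduce a simulation bit-identically:
#' the full parameter set, the scenario definition (initial state or
#' pre-equilibration directive, horizon, output grid, events), the
#' integration tolerances and the package version.
#'
#' @param traj A \code{ppgpp_trajectory}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{replay_manifest}}
#' @export
write_run_manifest <- function(traj, path) {
  stopifnot(inherits(traj, "ppgpp_trajectory"))
  sc <- traj$scenario
  ev <- lapply(sc$events, function(e)
    list(time = e$time, trigger_var = e$trigger_var,
         threshold = e$threshold, action = e$action, value = e$value,
         delay = e$delay))
  man <- list(
    package = "ppGppSim",
    version = as.character(utils::packageVersion("ppGppSim")),
    parameters = unclass(sc$params),
    init = if (identical(sc$init, "pre-equilibrate")) "pre-equilibrate"
           else as.list(unclass(sc$init)),
    t_end = sc$t_end, output_dt = sc$output_dt, events = ev,
    rtol = traj$rtol, atol = traj$atol)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Re-run a simulation from a manifest
#'
#' Rebuilds the scenario recorded by \code{\link{write_run_manifest}} and
#' re-integrates it. The simulator is deterministic, so the replayed
#' trajectory (and any CSV written from it) is bit-identical to the
#' original on the same platform.
#'
#' @param path Manifest JSON path.
#' @return A \code{ppgpp_trajectory}.
#' @export
replay_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- as.list(man$parameters)
  p$ACP_conserved <- isTRUE(p$ACP_conserved)
  validate_parameters(p)
  p <- structure(p, class = "ppgpp_parameters")
  init <- if (identical(man$init, "pre-equilibrate")) "pre-equilibrate"
          else structure(unlist(man$init)[state_names()],
                         class = "ppgpp_state")
  events <- list()
  if (length(man$events)) {
    evs <- man$events
    if (is.data.frame(evs)) evs <- split(evs, seq_len(nrow(evs)))
    events <- lapply(evs, function(e) {
      val <- if (is.null(e$value) || is.na(e$value)) NULL else e$value
      if (!is.null(e$trigger_var) && !is.na(e$trigger_var))
        event_when(e$trigger_var, e$threshold, e$action, val,
                   delay = if (is.null(e$delay)) 0 else e$delay)
      else event_at(e$time, e$action, val)
    })
    names(events) <- NULL
  }
  sc <- scenario(p, init = init, t_end = man$t_end,
                 output_dt = man$output_dt, events = events)
  simulate_scenario(sc, rtol = man$rtol, atol = man$atol)
}
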