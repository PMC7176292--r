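#' Binding/unbinding event detection with hysteresis
#'
#' Two-threshold hysteresis automaton on a monitored inter-atom distance:
#' the unbound state switches to bound when the distance drops below
#' \code{bound_thresh} (a binding event) and bound switches to unbound when
#' it exceeds \code{unbound_thresh} (an unbinding event). Distances inside
#' the dead zone never change the state, so boundary chatter is not
#' counted. The series starts unbound (ligand placed in solvent) unless
#' stated otherwise.
#'
#' @param distances numeric distance series, Angstrom.
#' @param times optional time stamps (ps); defaults to the sample index.
#' @param bound_thresh bound threshold, Angstrom (default 4).
#' @param unbound_thresh unbound threshold, Angstrom (default 10); must
#'   exceed \code{bound_thresh}.
#' @param initial_state \code{"unbound"} (default) or \code{"bound"}.
#' @return an object of class \code{event_series}: per-frame \code{state},
#'   the \code{events} table (type, time, index), and counts
#'   \code{n_binding}, \code{n_unbinding}, \code{n_events}.
#' @export
detect_events <- function(distances, times = NULL, bound_thresh = 4,
                          unbound_thresh = 10,
                          initial_state = c("unbound", "bound")) {
  if (any(!is.finite(distances))) stop("non-finite distance in series")
  if (unbound_thresh <= bound_thresh)
    stop("'unbound_thresh' must exceed 'bound_thresh'")
  initial_state <- match.arg(initial_state)
  n <- length(distances)
  if (is.null(times)) times <- seq_len(n)
  # hysteresis as last-observation-carried-forward over decisive samples
  cand <- ifelse(distances < bound_thresh, 1L,
                 ifelse(distances > unbound_thresh, 0L, NA_integer_))
  init <- if (initial_state == "bound") 1L else 0L
  known <- !is.na(cand)
  vals <- c(init, cand[known])
  state_int <- vals[cumsum(known) + 1L]
  state <- ifelse(state_int == 1L, "bound", "unbound")
  flips <- which(diff(c(init, state_int)) != 0L)
  events <- data.frame(
    type = ifelse(state_int[flips] == 1L, "binding", "unbinding"),
    time = times[flips], index = flips,
    stringsAsFactors = FALSE
  )
  structure(list(times = times, distances = distances, state = state,
                 events = events,
                 n_binding = sum(events$type == "binding"),
                 n_unbinding = sum(events$type == "unbinding"),
                 n_events = nrow(events),
                 bound_thresh = bound_thresh,
                 unbound_thresh = unbound_thresh,
                 initial_state = initial_state),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("event series: %d binding + %d unbinding events over %d frames (<%g A bound, >%g A unbound)\n",
              x$n_binding, x$n_unbinding, length(x$distances),
              x$bound_thresh, x$unbound_thresh))
  invisible(x)
}

#' Sampling efficiency in events per microsecond
#'
#' Total event count (bindings + unbindings) per unit simulation time,
#' with an optional ratio against a reference rate (e.g. an unbiased run)
#' for relative-efficiency comparisons.
#'
#' @param events an \code{event_series}.
#' @param sim_time_us simulated time in microseconds (> 0).
#' @param reference_rate optional reference rate, events per microsecond.
#' @return list with \code{events_per_us} and (when a reference is given)
#'   \code{ratio_vs_reference}.
#' @export
efficiency <- function(events, sim_time_us, reference_rate = NULL) {
  stopifnot(inherits(events, "event_series"))
  if (!is.numeric(sim_time_us) || sim_time_us <= 0)
    stop("'sim_time_us' must be positive")
  rate <- events$n_events / sim_time_us
  out <- list(events_per_us = rate)
  if (!is.null(reference_rate))
    out$ratio_vs_reference <- if (reference_rate > 0) rate / reference_rate
                              else Inf * (rate > 0)
  out
}

#' Fill-limit calibration scan
#'
#' Runs mABP at each fill-limit (and seed), counts binding/unbinding
#' events on the system's monitored distance, and reports whether the
#' per-run landscape places a basin inside the declared target region.
#' A fill-limit of 0 disables the bias entirely (the run is identical to
#' the unbiased integrator at the same seed). The scan exposes the
#' calibration regimes: at very low fill-limit the bias cannot carry the
#' ligand over the entrance barrier (no events); at a calibrated
#' fill-limit events occur and the pocket basin is found; at very high
#' fill-limit sampling spreads over the spurious-escape channel.
#'
#' @param system a \code{toy_system} with a monitored distance (kind
#'   \code{"host_guest"}).
#' @param flim_values numeric fill-limits, kcal/mol (at least 2; 0 means
#'   unbiased).
#' @param n_steps steps per run.
#' @param seeds integer vector of seeds (one run per flim x seed).
#' @param target_region \code{basin_region} around the pocket in CV space;
#'   defaults to the cell block around the system's constructed pose.
#' @param stride save stride.
#' @param ... grid overrides passed to \code{\link{system_grid}}.
#' @return an object of class \code{flim_scan}: \code{table} (flim, seed,
#'   bindings, unbindings, events_per_us, basin_found) and
#'   \code{fes_by_flim} (replicate-averaged landscape per nonzero flim).
#' @export
flim_scan <- function(system, flim_values, n_steps, seeds = 1:3,
                      target_region = NULL, stride = 10L, ...) {
  stopifnot(inherits(system, "toy_system"))
  if (system$kind != "host_guest")
    stop("fill-limit scans require a system with a monitored distance")
  if (length(flim_values) < 2L) stop("need at least 2 fill-limit values")
  if (is.null(target_region)) {
    hw <- 1.5
    target_region <- basin_region(system$pose_cv - hw, system$pose_cv + hw,
                                  label = "pocket")
  }
  rows <- list()
  fes_by_flim <- list()
  for (fl in flim_values) {
    reps <- list()
    for (sd in seeds) {
      if (fl > 0) {
        grid <- system_grid(system, flim = fl, ...)
        res <- run_mabp(system, grid, n_steps, stride = stride, seed = sd)
        traj <- res$trajectory
        fes <- free_energy_estimate(res$grid)
        reps[[length(reps) + 1L]] <- fes
        basins <- find_minima(fes, depth_threshold = Inf)
        found <- any(vapply(basins, function(b)
          region_contains(target_region, matrix(b$minimum, nrow = 1L)),
          logical(1)))
      } else {
        traj <- run_unbiased(system, n_steps, stride = stride, seed = sd)
        found <- FALSE
      }
      ev <- detect_events(traj$monitor,
                          times = seq_along(traj$monitor) * stride * system$dt)
      sim_us <- n_steps * system$dt * 1e-6
      rows[[length(rows) + 1L]] <- data.frame(
        flim = fl, seed = sd, bindings = ev$n_binding,
        unbindings = ev$n_unbinding,
        events_per_us = efficiency(ev, sim_us)$events_per_us,
        basin_found = found
      )
    }
    if (length(reps) > 0L)
      fes_by_flim[[sprintf("%g", fl)]] <- average_landscapes(reps)
  }
  structure(list(table = do.call(rbind, rows), fes_by_flim = fes_by_flim,
                 target_region = target_region),
            class = "flim_scan")
}

#' @export
print.flim_scan <- function(x, ...) {
  cat("fill-limit calibration scan:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a fill-limit scan report as TSV
#'
#' @param scan a \code{flim_scan}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_scan_report <- function(scan, path) {
  stopifnot(inherits(scan, "flim_scan"))
  write.table(scan$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
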