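# Trap-array filling, valve-controlled release/re-trap logic, and the
# particle-size / channel-dimension occupancy classifier.
#
# Units are serially connected along the main flow: a particle travels
# downstream past each unit in order; at every unit it either enters the
# trap (empty, valve off) or is shunted through the bypass loop to the next
# unit.  An occupied trap or an activated valve blocks Path 1 completely,
# so everything downstream of the decision is pure routing logic.

#' Create a trap-array state
#'
#' @param n_units number of serially connected trapping units.
#' @param unit the [trap_unit()] geometry shared by all units.
#' @param p_trap probability that a particle arriving at an empty,
#'   valve-off unit enters the trap (used by `mode = "stochastic"`
#'   routing); defaults to the hydraulic flow split Q1/(Q1+Q2) of `unit`.
#' @param fluid a [fluid_spec()] for the default split.
#' @return Object of class `trap_array`: `$units` tibble (unit, occupied,
#'   valve_on), `$p_trap`, and an append-only `$log` tibble.
#' @export
trap_array <- function(n_units, unit = trap_unit(1, 15), p_trap = NULL,
                       fluid = fluid_water()) {
  stopifnot(n_units >= 1)
  if (is.null(p_trap)) {
    fs <- flow_split(unit, fluid)
    p_trap <- fs$Q1 / (fs$Q1 + fs$Q2)
  }
  structure(list(
    units = tibble::tibble(unit = seq_len(n_units), occupied = NA_integer_,
                           valve_on = FALSE),
    p_trap = p_trap, unit_geometry = unit, clock = 0,
    log = tibble::tibble(time = numeric(), particle = integer(),
                         unit = integer(), event = character())
  ), class = "trap_array")
}

#' @export
print.trap_array <- function(x, ...) {
  occ <- sum(!is.na(x$units$occupied))
  cat(sprintf("<trap_array> %d units, %d occupied, %d valves on, p_trap = %.3f\n",
              nrow(x$units), occ, sum(x$units$valve_on), x$p_trap))
  invisible(x)
}

#' @method tidy trap_array
#' @export
tidy.trap_array <- function(x, ...) x$units

#' @method glance trap_array
#' @export
glance.trap_array <- function(x, ...) {
  tibble::tibble(
    n_units = nrow(x$units),
    n_occupied = sum(!is.na(x$units$occupied)),
    n_valve_on = sum(x$units$valve_on),
    single_occupancy_fraction = mean(!is.na(x$units$occupied)),
    p_trap = x$p_trap,
    n_events = nrow(x$log)
  )
}

log_event <- function(state, particle, unit, event) {
  state$log <- dplyr::bind_rows(state$log, tibble::tibble(
    time = state$clock, particle = as.integer(particle),
    unit = as.integer(unit), event = event))
  state
}

#' Route one particle at one unit
#'
#' An occupied trap or an activated valve always shunts the particle to the
#' bypass.  At an empty, valve-off unit: `deterministic` mode follows the
#' larger of Q1/Q2 (trap if p_trap > 0.5), `stochastic` mode enters the
#' trap with probability Q1/(Q1+Q2).
#'
#' @param state a [trap_array()].
#' @param unit_index which unit the particle has reached.
#' @param mode `"deterministic"` or `"stochastic"`.
#' @return `"trap"` or `"bypass"`.
#' @export
route_particle <- function(state, unit_index,
                           mode = c("deterministic", "stochastic")) {
  mode <- match.arg(mode)
  row <- state$units[unit_index, ]
  if (!is.na(row$occupied) || row$valve_on) return("bypass")
  if (mode == "deterministic") {
    if (state$p_trap > 0.5) "trap" else "bypass"
  } else {
    if (stats::runif(1) < state$p_trap) "trap" else "bypass"
  }
}

# drive one particle from `from_unit` downstream to a trap or out of the array
advance_particle <- function(state, particle, from_unit, mode,
                             respect_valves = TRUE) {
  n <- nrow(state$units)
  i <- from_unit
  while (i <= n) {
    decision <- route_particle(state, i, mode)
    if (decision == "trap") {
      state$units$occupied[i] <- as.integer(particle)
      state <- log_event(state, particle, i, "trap")
      return(state)
    }
    state <- log_event(state, particle, i, "bypass")
    i <- i + 1L
  }
  log_event(state, particle, n, "exit")
}

#' Sequential filling of a trap array
#'
#' Injects particles one at a time at the array head; each traverses the
#' units in order under [route_particle()] until it is trapped or exits.
#'
#' @param state a [trap_array()] (or an integer, shorthand for
#'   `trap_array(n_units = state)`).
#' @param n_particles particles injected.
#' @param mode routing mode, see [route_particle()].
#' @param seed RNG seed for stochastic routing.
#' @return The updated `trap_array` with its event log.
#' @export
fill_simulation <- function(state, n_particles,
                            mode = c("deterministic", "stochastic"),
                            seed = 1L) {
  mode <- match.arg(mode)
  if (is.numeric(state) && length(state) == 1L) state <- trap_array(state)
  stopifnot(n_particles >= 1)
  set.seed(seed)
  next_id <- max(c(0L, state$log$particle)) + 1L
  for (p in seq_len(n_particles)) {
    state$clock <- state$clock + 1
    state <- advance_particle(state, next_id, 1L, mode)
    next_id <- next_id + 1L
  }
  state
}

#' Valve schedule for selective release
#'
#' @param unit units to actuate, in order.
#' @param time optional actuation times (defaults to sequence order).
#' @param action `"open_close"` pulses the valve (release then reopen);
#'   `"on"`/`"off"` latch it.
#' @return A tibble with columns `time`, `unit`, `action`.
#' @export
release_schedule <- function(unit, time = seq_along(unit),
                             action = "open_close") {
  tibble::tibble(time = time, unit = as.integer(unit),
                 action = rep(action, length.out = length(unit)))
}

#' Valve-controlled release (and possible downstream re-trapping)
#'
#' Actuating the valve of an occupied unit ejects its particle into the
#' main flow; the particle then traverses the downstream units under the
#' ordinary routing rule, so it can be re-trapped by an empty valve-off
#' trap downstream.  With `guard_downstream = TRUE` the valves of all empty
#' downstream units are held on while the particle passes, so a released
#' particle always leaves the array (release order becomes irrelevant).
#'
#' @param state a [trap_array()].
#' @param schedule a [release_schedule()] (or tibble with `time`, `unit`,
#'   `action` columns; `"on"`, `"off"`, `"open_close"`).
#' @param guard_downstream protect empty downstream traps during each
#'   release.
#' @param mode routing mode for the released particle.
#' @return The updated `trap_array`.
#' @export
release <- function(state, schedule, guard_downstream = FALSE,
                    mode = "deterministic") {
  stopifnot(all(c("time", "unit", "action") %in% names(schedule)))
  if (any(schedule$unit < 1 | schedule$unit > nrow(state$units))) {
    rlang::abort("schedule references units outside the array",
                 class = "traploop_invalid_argument")
  }
  schedule <- dplyr::arrange(schedule, .data$time)
  for (k in seq_len(nrow(schedule))) {
    u <- schedule$unit[k]
    act <- schedule$action[k]
    state$clock <- max(state$clock, schedule$time[k])  # log time stays monotone
    if (act == "on") { state$units$valve_on[u] <- TRUE }
    if (act == "off") { state$units$valve_on[u] <- FALSE; next }
    p <- state$units$occupied[u]
    if (act %in% c("on", "open_close")) {
      if (is.na(p)) {
        if (act == "open_close") {
          rlang::warn(sprintf("release at empty unit %d: no-op", u))
        }
        next
      }
      # eject into the main flow
      state$units$occupied[u] <- NA_integer_
      state$units$valve_on[u] <- TRUE
      state <- log_event(state, p, u, "release")
      saved <- state$units$valve_on
      if (guard_downstream) {
        downstream_empty <- state$units$unit > u & is.na(state$units$occupied)
        state$units$valve_on[downstream_empty] <- TRUE
      }
      if (u < nrow(state$units)) {
        state <- advance_particle(state, p, u + 1L, mode)
      } else {
        state <- log_event(state, p, u, "exit")
      }
      state$units$valve_on <- saved
      if (act == "open_close") state$units$valve_on[u] <- FALSE
    }
  }
  state
}

#' Replay an event log
#'
#' Rebuilds the occupancy state implied by an event log, verifying that the
#' log is a consistent history (used to check reproducibility).
#'
#' @param state a [trap_array()] whose `$log` to replay (geometry and
#'   p_trap are reused).
#' @return A `trap_array` whose occupancy matches the logged history.
#' @export
replay_log <- function(state) {
  fresh <- trap_array(nrow(state$units), state$unit_geometry,
                      p_trap = state$p_trap)
  for (k in seq_len(nrow(state$log))) {
    ev <- state$log[k, ]
    if (ev$event == "trap") fresh$units$occupied[ev$unit] <- ev$particle
    if (ev$event == "release") {
      occ <- fresh$units$occupied
      occ[ev$unit] <- NA_integer_
      fresh$units$occupied <- occ
    }
  }
  fresh$log <- state$log
  fresh$clock <- state$clock
  fresh
}

#' Classify how a particle fits the trap geometry
#'
#' Distils the empirical occupancy heuristics: the trapping gap must be
#' smaller than the particle (else it passes through); the entrance width
#' and channel height should exceed the particle size but stay below twice
#' of it, otherwise several particles share a trap (stacked vertically when
#' the height allows it, side by side when the entrance does); particles
#' close to the channel dimensions risk clogging the device.
#'
#' @param particle_diameter,gap,entrance_width,height dimensions in um.
#' @param blockage_factor particles larger than this fraction of the
#'   narrowest channel dimension are flagged as blockage risks (heuristic).
#' @return One-row tibble of class `fit_class`: `label` (primary class),
#'   `labels` (all applicable, comma-separated), `capacity` (particles per
#'   trap implied by the class) and `rationale`.
#' @export
classify_fit <- function(particle_diameter, gap, entrance_width, height,
                         blockage_factor = 0.8) {
  stopifnot(particle_diameter > 0, gap > 0, entrance_width > 0, height > 0)
  d <- particle_diameter
  labs <- character()
  why <- character()
  if (d <= gap) {
    labs <- "passes_gap"
    why <- sprintf("particle (%g um) fits through the %g um trapping gap", d, gap)
  } else {
    if (d >= blockage_factor * min(entrance_width, height)) {
      labs <- c(labs, "blockage_risk")
      why <- c(why, sprintf(
        "particle (%g um) is >= %g x the narrowest channel dimension (%g um)",
        d, blockage_factor, min(entrance_width, height)))
    }
    if (height >= 2 * d) {
      labs <- c(labs, "multiple_vertical")
      why <- c(why, sprintf(
        "channel height (%g um) is at least twice the particle (%g um): stacking", height, d))
    }
    if (entrance_width >= 2 * d) {
      labs <- c(labs, "multiple_lateral")
      why <- c(why, sprintf(
        "trap entrance (%g um) is at least twice the particle (%g um): side-by-side", entrance_width, d))
    }
    if (!length(labs)) {
      labs <- "single"
      why <- sprintf(
        "gap < particle < channel dimensions < 2 x particle: single occupancy expected (%g um in %g/%g um channel)",
        d, entrance_width, height)
    }
  }
  capacity <- if (labs[1] %in% c("passes_gap", "blockage_risk")) 0L else
    (1L + ("multiple_vertical" %in% labs) + ("multiple_lateral" %in% labs))
  # priority: passes_gap > blockage_risk > multiple_* > single
  tibble::new_tibble(tibble::tibble(
    label = labs[1], labels = paste(labs, collapse = ","),
    capacity = capacity, rationale = paste(why, collapse = "; ")),
    class = "fit_class")
}
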