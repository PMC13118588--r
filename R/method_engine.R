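# Step vocabulary: required/optional parameters and their checks. Each
# validator returns NULL or a character violation message.
step_vocabulary <- function(syringe_capacity = 25) {
  num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  vol_ok <- function(x) {
    v <- tryCatch(as_microliters(x), error = function(e) NA)
    if (is.na(v)) return("unparseable volume")
    if (v < 0) return("volume must be nonnegative")
    if (v > syringe_capacity) {
      return(sprintf("volume %g uL exceeds syringe capacity %g uL", v, syringe_capacity))
    }
    NULL
  }
  list(
    move_to_well = list(
      required = c("labware", "well"),
      check = function(p) {
        tryCatch({ well_address(p$well); NULL },
                 error = function(e) conditionMessage(e))
      }
    ),
    aspirate = list(required = "volume", check = function(p) vol_ok(p$volume)),
    dispense = list(required = "volume", check = function(p) vol_ok(p$volume)),
    valve_two_position = list(
      required = "position",
      check = function(p) {
        if (!toupper(p$position) %in% c("A", "B")) "position must be A or B" else NULL
      }
    ),
    valve_selector = list(
      required = "port",
      check = function(p) {
        if (!num(p$port) || p$port < 1 || p$port > 8) "port must be in 1..8" else NULL
      }
    ),
    set_output = list(
      required = c("pin", "level"),
      check = function(p) {
        if (!p$level %in% c(0, 1)) "level must be 0 or 1" else NULL
      }
    ),
    pulse_relay = list(
      required = character(),
      check = function(p) {
        if (!is.null(p$duration) && (!num(p$duration) || p$duration <= 0)) {
          "duration must be a positive number of seconds"
        } else NULL
      }
    ),
    wait_input = list(
      required = c("pin", "level", "timeout"),
      check = function(p) {
        if (!num(p$timeout) || p$timeout <= 0) "timeout must be positive" else NULL
      }
    ),
    set_temp = list(
      required = "celsius",
      check = function(p) {
        if (!num(p$celsius) || p$celsius < -20 || p$celsius > 110) {
          "temperature must be within [-20, 110] C"
        } else NULL
      }
    ),
    punch_foil = list(
      required = c("labware", "well"),
      check = function(p) {
        tryCatch({ well_address(p$well); NULL },
                 error = function(e) conditionMessage(e))
      }
    ),
    pause = list(
      required = "duration",
      check = function(p) {
        if (!num(p$duration) || p$duration < 0) "duration must be nonnegative" else NULL
      }
    ),
    comment = list(required = "text", check = function(p) NULL)
  )
}

validate_steps <- function(steps, syringe_capacity = 25) {
  vocab <- step_vocabulary(syringe_capacity)
  violations <- character(0)
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    name <- s$step
    if (is.null(name) || !name %in% names(vocab)) {
      violations <- c(violations,
                      sprintf("step %d: unknown step name %s", i,
                              dQuote(name %||% "<missing>")))
      next
    }
    spec <- vocab[[name]]
    missing <- setdiff(spec$required, names(s))
    if (length(missing) > 0) {
      violations <- c(violations,
                      sprintf("step %d (%s): missing parameter(s) %s",
                              i, name, paste(missing, collapse = ", ")))
      next
    }
    msg <- spec$check(s)
    if (!is.null(msg)) {
      violations <- c(violations, sprintf("step %d (%s): %s", i, name, msg))
    }
  }
  violations
}

#' Method programs
#'
#' A method program is a named, ordered list of steps from a fixed
#' vocabulary (`move_to_well`, `aspirate`, `dispense`,
#' `valve_two_position`, `valve_selector`, `set_output`, `pulse_relay`,
#' `wait_input`, `set_temp`, `punch_foil`, `pause`, `comment`). All step
#' parameters are validated before execution begins (fail-fast), so a
#' program that parses cannot mutate device state and then fail on a
#' malformed step.
#'
#' @param name program name.
#' @param steps list of step lists, each with a `step` field naming the
#'   step and its parameters.
#' @param syringe_capacity_ul capacity used to validate volumes at parse
#'   time, uL.
#' @return a `method_program`.
#' @export
method_program <- function(name, steps, syringe_capacity_ul = 25) {
  violations <- validate_steps(steps, syringe_capacity_ul)
  if (length(violations) > 0) {
    stop_nanosampler(
      paste(c("invalid method program:", violations), collapse = "\n  "),
      "method_validation"
    )
  }
  structure(list(name = name, steps = steps), class = "method_program")
}

#' @export
print.method_program <- function(x, ...) {
  cat(sprintf("<method_program> %s: %d step(s)\n", x$name, length(x$steps)))
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    params <- s[setdiff(names(s), "step")]
    cat(sprintf("  %2d. %s %s\n", i, s$step,
                paste(sprintf("%s=%s", names(params), unlist(params)), collapse = " ")))
  }
  invisible(x)
}

#' Parse and serialize method files
#'
#' Method files are YAML: a `name` plus a `steps` list with one step per
#' item. Parse errors and validation violations are reported together
#' with their step index; a file that fails validation is rejected as a
#' whole. `write_method()` serializes a program back to YAML such that
#' `parse_method(write_method(x))` is semantically identical to `x`.
#'
#' @param text YAML text (character scalar, possibly multi-line).
#' @param syringe_capacity_ul syringe capacity for volume validation, uL.
#' @return a [method_program()].
#' @export
parse_method <- function(text, syringe_capacity_ul = 25) {
  doc <- tryCatch(
    yaml::yaml.load(paste(text, collapse = "\n")),
    error = function(e) {
      stop_nanosampler(sprintf("method file does not parse as YAML: %s",
                               conditionMessage(e)), "parse_error")
    }
  )
  if (is.null(doc)) {
    return(method_program("empty", list(), syringe_capacity_ul))
  }
  steps <- doc$steps %||% list()
  method_program(doc$name %||% "unnamed", steps, syringe_capacity_ul)
}

#' @rdname parse_method
#' @param path path to a YAML method file.
#' @export
parse_method_file <- function(path, syringe_capacity_ul = 25) {
  if (!file.exists(path)) {
    stop_nanosampler(sprintf("method file %s does not exist", dQuote(path)), "io_error")
  }
  parse_method(readLines(path, warn = FALSE), syringe_capacity_ul)
}

#' @rdname parse_method
#' @param program a [method_program()].
#' @export
write_method <- function(program, path = NULL) {
  txt <- yaml::as.yaml(list(name = program$name, steps = program$steps))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(path))
  }
  txt
}

#' Assemble a simulated sampler system
#'
#' Bundles the simulated devices, fluid network, calibration registry and
#' labware definitions into one system that [execute()] drives. Per the
#' restart rules, the system starts with an *empty* calibration registry
#' and *no* syringe profile: saved calibrations must be loaded explicitly
#' and the syringe recalibrated each session.
#'
#' @param network a [fluid_network()].
#' @param relay_pin output pin wired to the pump-start relay.
#' @param pump_done_pin input pin carrying the pump end-of-method signal.
#' @param tool_offsets named list of XYZ tool offsets (mm); the foil
#'   puncher rides beside the needle with its own offset and plunge depth.
#' @param punch_depth_mm how far the puncher plunges below the well top.
#' @return a `sampler_system`.
#' @export
sampler_system <- function(network = fluid_network(),
                           relay_pin = 5, pump_done_pin = 7,
                           tool_offsets = list(needle = c(0, 0, 0),
                                               puncher = c(30, 0, -5)),
                           punch_depth_mm = 2) {
  clock <- virtual_clock()
  recorder <- trace_recorder()
  bridge <- signal_bridge(clock, recorder)
  bridge$configure_pin(relay_pin, "output")
  bridge$configure_pin(pump_done_pin, "input")
  state <- new.env(parent = emptyenv())
  state$plugs <- plug_state()
  state$syringe_fill_ul <- 0
  state$sealed <- list()
  state$pump <- NULL
  structure(
    list(
      clock = clock,
      recorder = recorder,
      motion = motion_controller(clock, recorder),
      selector = selector_valve(clock, recorder),
      two_position = two_position_valve(clock, recorder),
      bridge = bridge,
      tempdeck = tempdeck(clock, recorder),
      network = network,
      registry = calibration_registry(),
      labware = new.env(parent = emptyenv()),
      syringe = NULL,
      relay_pin = relay_pin,
      pump_done_pin = pump_done_pin,
      tool_offsets = tool_offsets,
      punch_depth_mm = punch_depth_mm,
      state = state
    ),
    class = "sampler_system"
  )
}

#' @rdname sampler_system
#' @param system a `sampler_system`.
#' @param labware a [labware_definition()].
#' @param sealed are the wells foil-sealed initially?
#' @export
add_labware <- function(system, labware, sealed = FALSE) {
  assign(labware$name, labware, envir = system$labware)
  system$state$sealed[[labware$name]] <-
    matrix(sealed, nrow = labware$rows, ncol = labware$columns)
  invisible(system)
}

#' @rdname sampler_system
#' @param profile a [syringe_profile()] from [calibrate_syringe()].
#' @export
set_syringe <- function(system, profile) {
  stopifnot(inherits(profile, "syringe_profile"))
  system$syringe <- profile
  # list element replaced by value semantics; store in state env instead
  system$state$syringe <- profile
  invisible(system)
}

#' @rdname sampler_system
#' @param pump_profile a [gradient_profile()] the scripted pump runs when
#'   the relay fires; the end-of-method signal is scheduled at pulse time
#'   plus the profile duration.
#' @export
attach_pump <- function(system, pump_profile = lc_gradient_default()) {
  system$state$pump <- list(
    profile = pump_profile,
    duration_s = (max(pump_profile$time_min) - min(pump_profile$time_min)) * 60
  )
  invisible(system)
}

get_syringe <- function(system) system$state$syringe %||% system$syringe

#' Execute a method program against the simulated system
#'
#' Runs steps strictly in order on the virtual clock, recording every
#' device state transition in an execution trace. Pre-flight validation —
#' all referenced labware defined and calibrated, syringe calibrated if
#' any liquid step is present — happens before any device command, so a
#' rejected program leaves device state untouched. `wait_input` suspends
#' the virtual clock until the scripted pump signal (or times out);
#' `pulse_relay` triggers the attached pump's gradient and schedules its
#' end-of-method signal.
#'
#' @param program a [method_program()].
#' @param system a [sampler_system()].
#' @return an `execution_trace`: list with `$entries` (tibble: time,
#'   step_index, device, command, outcome), `$totals` (aspirated /
#'   dispensed / loop throughput volumes, valve actuations, relay pulses,
#'   signals), `$aborted` flag and `$error` message if aborted.
#' @export
execute <- function(program, system) {
  stopifnot(inherits(program, "method_program"), inherits(system, "sampler_system"))
  # ---- pre-flight, before any device command ----
  referenced <- unique(unlist(lapply(program$steps, function(s) {
    if (s$step %in% c("move_to_well", "punch_foil")) s$labware else NULL
  })))
  for (lw in referenced) {
    if (!exists(lw, envir = system$labware, inherits = FALSE)) {
      stop_nanosampler(sprintf("labware %s is not defined on the deck", dQuote(lw)),
                       "preflight_error")
    }
    if (is.null(get_calibration(system$registry, lw))) {
      stop_nanosampler(sprintf("labware %s is not calibrated", dQuote(lw)),
                       "preflight_error")
    }
  }
  liquid_steps <- any(vapply(program$steps, function(s)
    s$step %in% c("aspirate", "dispense"), logical(1)))
  if (liquid_steps && is.null(get_syringe(system))) {
    stop_nanosampler("syringe is not calibrated; calibrate it before running methods",
                     "preflight_error")
  }
  if (!system$motion$is_homed(c("X", "Y", "Z", "P")) &&
      any(vapply(program$steps, function(s)
        s$step %in% c("move_to_well", "punch_foil", "aspirate", "dispense"),
        logical(1)))) {
    system$motion$home("ALL")
  }

  n0 <- length(system$recorder$entries)
  counts0 <- list(sel = system$selector$actuation_count,
                  tp = system$two_position$actuation_count)
  totals <- list(aspirated_ul = 0, dispensed_ul = 0, loop_volume_ul = 0,
                 plug_volume_expelled_ul = 0,
                 relay_pulses = 0L, signals_received = 0L)
  aborted <- FALSE
  error_msg <- NULL

  for (i in seq_along(program$steps)) {
    system$recorder$step_index <- i
    s <- program$steps[[i]]
    res <- tryCatch(
      {
        totals <- run_step(s, system, totals)
        NULL
      },
      nanosampler_error = function(e) e
    )
    if (!is.null(res)) {
      aborted <- TRUE
      error_msg <- sprintf("step %d (%s): %s", i, s$step, conditionMessage(res))
      system$recorder$record(system$clock$now, "engine", s$step,
                             paste("ABORT", error_msg))
      break
    }
  }
  system$recorder$step_index <- NA_integer_

  entries <- system$recorder$as_tibble()
  entries <- entries[seq_len(nrow(entries)) > n0, ]
  totals$valve_actuations <-
    (system$selector$actuation_count - counts0$sel) +
    (system$two_position$actuation_count - counts0$tp)
  structure(
    list(name = program$name, entries = entries, totals = totals,
         aborted = aborted, error = error_msg),
    class = "execution_trace"
  )
}

# Executes one step, returning the updated totals. Device errors abort
# the enclosing method.
run_step <- function(s, system, totals) {
  switch(s$step,
    move_to_well = {
      lw <- get(s$labware, envir = system$labware)
      cal <- get_calibration(system$registry, s$labware)
      target <- predict_well(cal, lw, s$well)
      tool <- s$tool %||% "needle"
      offset <- system$tool_offsets[[tool]] %||% c(0, 0, 0)
      move_to(system$motion, target, offset)
      totals
    },
    aspirate = totals_after_transfer(s, system, totals, "aspirate"),
    dispense = totals_after_transfer(s, system, totals, "dispense"),
    valve_two_position = { system$two_position$goto(s$position); totals },
    valve_selector = { system$selector$goto(s$port); totals },
    set_output = { system$bridge$set_output(s$pin, s$level); totals },
    pulse_relay = {
      t0 <- system$clock$now
      pulse_output(system$bridge, s$pin %||% system$relay_pin, s$duration %||% 0.5)
      pump <- system$state$pump
      if (!is.null(pump)) {
        system$bridge$script_event(t0 + pump$duration_s, system$pump_done_pin, 1L)
      }
      totals$relay_pulses <- totals$relay_pulses + 1L
      totals
    },
    wait_input = {
      out <- wait_for_input(system$bridge, s$pin, s$level, s$timeout)
      if (out$signaled) totals$signals_received <- totals$signals_received + 1L
      totals
    },
    set_temp = { system$tempdeck$set_temp(s$celsius); totals },
    punch_foil = {
      lw <- get(s$labware, envir = system$labware)
      cal <- get_calibration(system$registry, s$labware)
      target <- predict_well(cal, lw, s$well)
      target[3] <- target[3] - system$punch_depth_mm
      move_to(system$motion, target, system$tool_offsets$puncher %||% c(0, 0, 0))
      w <- well_address(s$well)
      system$state$sealed[[s$labware]][w$row, w$column] <- FALSE
      totals
    },
    pause = { system$clock$advance(s$duration); totals },
    comment = {
      system$recorder$record(system$clock$now, "engine", "comment", s$text)
      totals
    },
    stop_nanosampler(sprintf("unknown step %s", dQuote(s$step)), "method_validation")
  )
}

totals_after_transfer <- function(s, system, totals, direction) {
  vol <- as_microliters(s$volume)
  profile <- get_syringe(system)
  fill <- system$state$syringe_fill_ul
  new_fill <- if (direction == "aspirate") fill + vol else fill - vol
  if (new_fill < -1e-9 || new_fill > profile$nominal_volume + 1e-9) {
    stop_nanosampler(
      sprintf("%s %g uL would take the syringe fill to %g uL (capacity %g uL)",
              direction, vol, new_fill, profile$nominal_volume),
      "capacity_error"
    )
  }
  plunger_target <- system$motion$limits$p[1] + travel_for_volume(profile, new_fill)
  system$motion$move_plunger(plunger_target)
  system$state$syringe_fill_ul <- new_fill

  # plug bookkeeping: fluid moves plugs only when the syringe path reaches
  # the needle tip; loop throughput accrues when the loop is on that path
  path <- active_path(system$network, "needle", "syringe",
                      selector = system$selector$position,
                      two_position = system$two_position$position)
  if (!is.null(path)) {
    path_volume <- sum(path$volume_ul)
    label <- s$label %||% NULL
    system$state$plugs <- if (direction == "aspirate" && !is.null(label)) {
      aspirate_plug(system$state$plugs, vol, label, path_volume)
    } else {
      suppressWarnings(
        advance_plugs(system$state$plugs, vol, direction, path_volume)
      )
    }
    totals$plug_volume_expelled_ul <- totals$plug_volume_expelled_ul +
      (attr(system$state$plugs, "lost_volume_ul") %||% 0)
    if (any(path$label == "loop")) {
      totals$loop_volume_ul <- totals$loop_volume_ul + vol
    }
  }
  if (direction == "aspirate") {
    totals$aspirated_ul <- totals$aspirated_ul + vol
  } else {
    totals$dispensed_ul <- totals$dispensed_ul + vol
  }
  totals
}

#' @export
print.execution_trace <- function(x, ...) {
  cat(sprintf("<execution_trace> %s: %d entries%s\n", x$name, nrow(x$entries),
              if (x$aborted) " [ABORTED]" else ""))
  if (x$aborted) cat("  error:", x$error, "\n")
  cat(sprintf("  aspirated %.3f uL, dispensed %.3f uL, %.3f uL through loop\n",
              x$totals$aspirated_ul, x$totals$dispensed_ul, x$totals$loop_volume_ul))
  invisible(x)
}

#' @rdname execute
#' @param x an `execution_trace`.
#' @param ... unused.
#' @export
tidy.execution_trace <- function(x, ...) {
  x$entries
}

#' @rdname execute
#' @param object an `execution_trace`.
#' @export
glance.execution_trace <- function(object, ...) {
  tibble::tibble(
    name = object$name,
    n_entries = nrow(object$entries),
    aspirated_ul = object$totals$aspirated_ul,
    dispensed_ul = object$totals$dispensed_ul,
    loop_volume_ul = object$totals$loop_volume_ul,
    valve_actuations = object$totals$valve_actuations,
    relay_pulses = object$totals$relay_pulses,
    signals_received = object$totals$signals_received,
    aborted = object$aborted
  )
}

#' @rdname execute
#' @param trace an `execution_trace`.
#' @param path output CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(trace$entries, path)
  invisible(path)
}

#' Method queues
#'
#' Methods queue first-in-first-out. A failing method aborts itself and
#' halts the queue; the traces of completed (and the partially executed)
#' methods are returned together with the names of the methods left
#' unrun.
#'
#' @param programs list of [method_program()]s.
#' @return `queue_methods()` returns a `method_queue`.
#' @export
queue_methods <- function(programs = list()) {
  stopifnot(all(vapply(programs, inherits, logical(1), "method_program")))
  structure(list(programs = programs), class = "method_queue")
}

#' @rdname queue_methods
#' @param queue a `method_queue`.
#' @param system a [sampler_system()].
#' @return `run_queue()` returns a list of `execution_trace`s with an
#'   `unrun` attribute naming any methods skipped after a failure.
#' @export
run_queue <- function(queue, system) {
  traces <- list()
  unrun <- character(0)
  for (i in seq_along(queue$programs)) {
    prog <- queue$programs[[i]]
    trace <- tryCatch(execute(prog, system), nanosampler_error = function(e) e)
    if (inherits(trace, "error")) {
      # pre-flight rejection: record as an aborted, empty trace
      trace <- structure(
        list(name = prog$name,
             entries = system$recorder$as_tibble()[0, ],
             totals = list(aspirated_ul = 0, dispensed_ul = 0, loop_volume_ul = 0,
                           relay_pulses = 0L, signals_received = 0L,
                           valve_actuations = 0L),
             aborted = TRUE, error = conditionMessage(trace)),
        class = "execution_trace"
      )
    }
    traces[[prog$name]] <- trace
    if (trace$aborted) {
      if (i < length(queue$programs)) {
        unrun <- vapply(queue$programs[(i + 1):length(queue$programs)],
                        function(p) p$name, character(1))
      }
      break
    }
  }
  attr(traces, "unrun") <- unrun
  traces
}
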