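#' Virtual clock and trace recorder
#'
#' All simulated devices share a virtual clock advanced only by waits,
#' pauses and configured motion durations — never wall time — so every run
#' is instantaneous and bit-reproducible. The trace recorder accumulates
#' one entry per device state transition with the monotone simulated
#' timestamp at which it occurred.
#'
#' @param start start time in seconds.
#' @return a `VirtualClock` R6 object with `$now` and `$advance(dt)`.
#' @export
virtual_clock <- function(start = 0) VirtualClock$new(start)

VirtualClock <- R6::R6Class("VirtualClock",
  public = list(
    now = 0,
    initialize = function(start = 0) {
      self$now <- as.numeric(start)
    },
    advance = function(dt) {
      if (dt < 0) stop_nanosampler("the virtual clock cannot run backwards", "clock_error")
      self$now <- self$now + dt
      invisible(self$now)
    },
    advance_to = function(t) {
      self$advance(max(0, t - self$now))
    }
  )
)

#' @rdname virtual_clock
#' @export
trace_recorder <- function() TraceRecorder$new()

TraceRecorder <- R6::R6Class("TraceRecorder",
  public = list(
    entries = NULL,
    step_index = NA_integer_,
    initialize = function() {
      self$entries <- list()
    },
    record = function(time, device, command, outcome) {
      self$entries[[length(self$entries) + 1]] <- list(
        time = time, step_index = self$step_index,
        device = device, command = command, outcome = outcome
      )
      invisible(NULL)
    },
    as_tibble = function() {
      if (length(self$entries) == 0) {
        return(tibble::tibble(
          time = numeric(), step_index = integer(),
          device = character(), command = character(), outcome = character()
        ))
      }
      purrr::map_dfr(self$entries, tibble::as_tibble)
    }
  )
)

# Base class for the simulated instruments. The serial transport is a
# bespoke line protocol: each command yields exactly one "OK ..." or
# "ERR ..." response, and an erroneous command leaves state unchanged.
SimulatedDevice <- R6::R6Class("SimulatedDevice",
  public = list(
    device_id = NULL,
    clock = NULL,
    recorder = NULL,
    initialize = function(device_id, clock = virtual_clock(), recorder = NULL) {
      self$device_id <- device_id
      self$clock <- clock
      self$recorder <- recorder
    },
    log = function(command, outcome) {
      if (!is.null(self$recorder)) {
        self$recorder$record(self$clock$now, self$device_id, command, outcome)
      }
      invisible(NULL)
    },
    handle = function(verb, args) {
      list(ok = FALSE, message = sprintf("unknown command %s", verb))
    },
    dispatch = function(command_text) {
      parts <- strsplit(trimws(command_text), "\\s+")[[1]]
      if (length(parts) == 0) {
        return(list(ok = FALSE, message = "empty command"))
      }
      self$handle(toupper(parts[1]), parts[-1])
    },
    state = function() list()
  )
)

#' Send a textual command to a simulated device
#'
#' Devices speak a bespoke line-oriented protocol (documented per device);
#' each command yields exactly one acknowledgement (`"OK ..."`, possibly
#' carrying a queried value) or one error response (`"ERR ..."`), and an
#' erroneous command leaves the device state unchanged.
#'
#' @param device a simulated device.
#' @param command_text a single command line, e.g. `"HOME XYZ"`, `"GOTO 3"`,
#'   `"SWITCH"`, `"POS?"`.
#' @return the response line as a character scalar.
#' @export
send_command <- function(device, command_text) {
  stopifnot(inherits(device, "SimulatedDevice"))
  res <- device$dispatch(command_text)
  response <- if (isTRUE(res$ok)) {
    if (is.null(res$value)) "OK" else paste("OK", res$value)
  } else {
    paste("ERR", res$message)
  }
  device$log(command_text, response)
  response
}

#' Simulated motion controller
#'
#' Point-to-point XYZ gantry plus plunger axis. Moves are rejected before
#' homing and whenever the target (including any tool offset) violates the
#' per-axis soft limits; an accepted move advances the virtual clock by
#' `distance / speed`. Protocol: `HOME XYZ`, `HOME P`, `HOME ALL`,
#' `MOVE <x> <y> <z>`, `MOVEP <mm>`, `POS?`.
#'
#' @param clock a [virtual_clock()].
#' @param recorder optional [trace_recorder()].
#' @param limits list of per-axis soft limits, each `c(min, max)` in mm.
#' @param speed gantry speed, mm/s of straight-line travel.
#' @return a `MotionController` R6 object.
#' @export
motion_controller <- function(clock = virtual_clock(), recorder = NULL,
                              limits = list(x = c(0, 350), y = c(0, 350),
                                            z = c(0, 170), p = c(0, 60)),
                              speed = 100) {
  MotionController$new("motion", clock, recorder, limits, speed)
}

MotionController <- R6::R6Class("MotionController", inherit = SimulatedDevice,
  public = list(
    position = c(x = NA_real_, y = NA_real_, z = NA_real_),
    plunger = NA_real_,
    homed = c(X = FALSE, Y = FALSE, Z = FALSE, P = FALSE),
    limits = NULL,
    speed = NULL,
    initialize = function(device_id, clock, recorder, limits, speed) {
      super$initialize(device_id, clock, recorder)
      self$limits <- limits
      self$speed <- speed
    },
    is_homed = function(axis = c("X", "Y", "Z", "P")) {
      all(self$homed[axis])
    },
    home = function(axes = "XYZ") {
      if (grepl("P", axes, fixed = TRUE) || identical(axes, "ALL")) {
        self$plunger <- self$limits$p[1]
        self$homed["P"] <- TRUE
      }
      if (grepl("XYZ", axes, fixed = TRUE) || identical(axes, "ALL")) {
        self$position <- c(x = self$limits$x[1], y = self$limits$y[1],
                           z = self$limits$z[2])  # home high, at the axis origin
        self$homed[c("X", "Y", "Z")] <- TRUE
      }
      self$log(paste("HOME", axes), "OK")
      invisible(self)
    },
    move_to = function(target, tool_offset = c(0, 0, 0)) {
      if (!self$is_homed(c("X", "Y", "Z"))) {
        stop_nanosampler("gantry must be homed before moving", "not_homed")
      }
      target <- as.numeric(target) + as.numeric(tool_offset)
      lim <- self$limits
      ok <- target[1] >= lim$x[1] && target[1] <= lim$x[2] &&
            target[2] >= lim$y[1] && target[2] <= lim$y[2] &&
            target[3] >= lim$z[1] && target[3] <= lim$z[2]
      if (!ok) {
        self$log(sprintf("MOVE %.3f %.3f %.3f", target[1], target[2], target[3]),
                 "ERR soft-limit violation")
        stop_nanosampler(
          sprintf("target (%.3f, %.3f, %.3f) violates soft limits; position unchanged",
                  target[1], target[2], target[3]),
          "limit_violation"
        )
      }
      dist <- sqrt(sum((target - self$position)^2))
      self$clock$advance(dist / self$speed)
      self$position <- c(x = target[1], y = target[2], z = target[3])
      self$log(sprintf("MOVE %.3f %.3f %.3f", target[1], target[2], target[3]), "OK")
      tibble::tibble(time = self$clock$now,
                     x = target[1], y = target[2], z = target[3])
    },
    move_plunger = function(target_mm) {
      if (!self$is_homed("P")) {
        stop_nanosampler("plunger must be homed before moving", "not_homed")
      }
      if (target_mm < self$limits$p[1] || target_mm > self$limits$p[2]) {
        stop_nanosampler("plunger target outside soft limits", "limit_violation")
      }
      self$clock$advance(abs(target_mm - self$plunger) / self$speed)
      self$plunger <- target_mm
      self$log(sprintf("MOVEP %.4f", target_mm), "OK")
      invisible(self)
    },
    handle = function(verb, args) {
      switch(verb,
        HOME = {
          self$home(if (length(args)) args[1] else "ALL")
          list(ok = TRUE)
        },
        MOVE = {
          res <- tryCatch(self$move_to(as.numeric(args[1:3])),
                          nanosampler_error = function(e) e)
          if (inherits(res, "error")) list(ok = FALSE, message = conditionMessage(res))
          else list(ok = TRUE)
        },
        MOVEP = {
          res <- tryCatch(self$move_plunger(as.numeric(args[1])),
                          nanosampler_error = function(e) e)
          if (inherits(res, "error")) list(ok = FALSE, message = conditionMessage(res))
          else list(ok = TRUE)
        },
        "POS?" = list(ok = TRUE, value = paste(
          paste(sprintf("%.4f", self$position), collapse = " "),
          sprintf("P %.4f", self$plunger),
          paste("HOMED", paste(names(self$homed)[self$homed], collapse = ""))
        )),
        super$handle(verb, args)
      )
    },
    state = function() {
      list(position = self$position, plunger = self$plunger, homed = self$homed)
    }
  )
)

#' Simulated valve actuators
#'
#' An N-position selector valve (protocol `GOTO <1..N>`, `POS?`) and a
#' six-port two-position valve (protocol `GOTO A|B`, `SWITCH`, `POS?`).
#' Both count actuations; a command to the position already held is a
#' no-op that still acknowledges but does not actuate.
#'
#' @inheritParams motion_controller
#' @param n_ports number of selector positions (8 on the reference build).
#' @return an R6 valve object.
#' @export
selector_valve <- function(clock = virtual_clock(), recorder = NULL, n_ports = 8) {
  SelectorValve$new("selector", clock, recorder, n_ports)
}

SelectorValve <- R6::R6Class("SelectorValve", inherit = SimulatedDevice,
  public = list(
    n_ports = NULL,
    position = 1L,
    actuation_count = 0L,
    initialize = function(device_id, clock, recorder, n_ports) {
      super$initialize(device_id, clock, recorder)
      self$n_ports <- as.integer(n_ports)
    },
    goto = function(port) {
      port <- as.integer(port)
      if (is.na(port) || port < 1 || port > self$n_ports) {
        stop_nanosampler(sprintf("selector port must be in 1..%d", self$n_ports),
                         "valve_error")
      }
      if (port != self$position) {
        self$position <- port
        self$actuation_count <- self$actuation_count + 1L
      }
      self$log(paste("GOTO", port), "OK")
      invisible(self)
    },
    handle = function(verb, args) {
      switch(verb,
        GOTO = {
          res <- tryCatch(self$goto(args[1]), nanosampler_error = function(e) e)
          if (inherits(res, "error")) list(ok = FALSE, message = conditionMessage(res))
          else list(ok = TRUE)
        },
        "POS?" = list(ok = TRUE, value = as.character(self$position)),
        super$handle(verb, args)
      )
    },
    state = function() list(position = self$position, actuation_count = self$actuation_count)
  )
)

#' @rdname selector_valve
#' @export
two_position_valve <- function(clock = virtual_clock(), recorder = NULL) {
  TwoPositionValve$new("two_position", clock, recorder)
}

TwoPositionValve <- R6::R6Class("TwoPositionValve", inherit = SimulatedDevice,
  public = list(
    position = "A",
    actuation_count = 0L,
    switch_position = function() {
      self$position <- if (identical(self$position, "A")) "B" else "A"
      self$actuation_count <- self$actuation_count + 1L
      self$log("SWITCH", paste("OK", self$position))
      invisible(self)
    },
    goto = function(position) {
      position <- toupper(position)
      if (!position %in% c("A", "B")) {
        stop_nanosampler("two-position valve position must be A or B", "valve_error")
      }
      if (!identical(position, self$position)) {
        self$position <- position
        self$actuation_count <- self$actuation_count + 1L
      }
      self$log(paste("GOTO", position), "OK")
      invisible(self)
    },
    handle = function(verb, args) {
      switch(verb,
        SWITCH = {
          self$switch_position()
          list(ok = TRUE, value = self$position)
        },
        GOTO = {
          res <- tryCatch(self$goto(args[1]), nanosampler_error = function(e) e)
          if (inherits(res, "error")) list(ok = FALSE, message = conditionMessage(res))
          else list(ok = TRUE)
        },
        "POS?" = list(ok = TRUE, value = self$position),
        super$handle(verb, args)
      )
    },
    state = function() list(position = self$position, actuation_count = self$actuation_count)
  )
)

#' Simulated GPIO signal bridge
#'
#' Models the microcontroller that carries general-purpose digital I/O
#' between the control software and external instruments: relay triggers
#' out (e.g. starting the LC gradient method) and end-of-method signals in
#' from the pump. Input edges are *scripted*: a list of
#' `(time, pin, level)` events that fire in time order on the virtual
#' clock, which makes every handshake deterministic.
#'
#' @inheritParams motion_controller
#' @param scripted_events optional tibble/data.frame with columns `time`
#'   (s, virtual clock), `pin`, `level` (0/1).
#' @return a `SignalBridge` R6 object.
#' @export
signal_bridge <- function(clock = virtual_clock(), recorder = NULL,
                          scripted_events = NULL) {
  SignalBridge$new("bridge", clock, recorder, scripted_events)
}

SignalBridge <- R6::R6Class("SignalBridge", inherit = SimulatedDevice,
  public = list(
    pins = NULL,
    events = NULL,
    initialize = function(device_id, clock, recorder, scripted_events = NULL) {
      super$initialize(device_id, clock, recorder)
      self$pins <- new.env(parent = emptyenv())
      self$events <- tibble::tibble(time = numeric(), pin = integer(),
                                    level = integer(), fired = logical())
      if (!is.null(scripted_events) && nrow(scripted_events) > 0) {
        for (i in seq_len(nrow(scripted_events))) {
          self$script_event(scripted_events$time[i], scripted_events$pin[i],
                            scripted_events$level[i])
        }
      }
    },
    configure_pin = function(pin, mode = c("output", "input")) {
      mode <- match.arg(mode)
      assign(as.character(pin), list(mode = mode, level = 0L), envir = self$pins)
      self$log(sprintf("CONFIG %s %s", pin, mode), "OK")
      invisible(self)
    },
    pin_info = function(pin) {
      key <- as.character(pin)
      if (!exists(key, envir = self$pins, inherits = FALSE)) {
        stop_nanosampler(sprintf("pin %s is not configured", pin), "pin_error")
      }
      get(key, envir = self$pins, inherits = FALSE)
    },
    script_event = function(time, pin, level) {
      self$events <- dplyr::arrange(
        dplyr::bind_rows(self$events,
                         tibble::tibble(time = as.numeric(time), pin = as.integer(pin),
                                        level = as.integer(level), fired = FALSE)),
        .data$time
      )
      invisible(self)
    },
    set_output = function(pin, level) {
      info <- self$pin_info(pin)
      if (info$mode != "output") {
        stop_nanosampler(sprintf("pin %s is not configured as an output", pin), "pin_error")
      }
      info$level <- as.integer(level)
      assign(as.character(pin), info, envir = self$pins)
      self$log(sprintf("SET %s %d", pin, info$level), "OK")
      invisible(self)
    }
  )
)

#' Pulse a digital output
#'
#' Drives an output pin high for `duration` seconds and back low,
#' advancing the virtual clock; the rising and falling edges appear as two
#' ordered trace entries `duration` apart. Used to trigger the LC gradient
#' method through the relay module.
#'
#' @param bridge a [signal_bridge()].
#' @param pin output pin number (must be configured as output).
#' @param duration pulse width in seconds.
#' @return a two-row tibble of the rising and falling edge events.
#' @export
pulse_output <- function(bridge, pin, duration = 0.5) {
  t0 <- bridge$clock$now
  bridge$set_output(pin, 1L)
  bridge$clock$advance(duration)
  bridge$set_output(pin, 0L)
  tibble::tibble(time = c(t0, t0 + duration), pin = pin, level = c(1L, 0L))
}

#' Wait for a scripted input edge
#'
#' Suspends the virtual clock until the next scripted event drives `pin`
#' to `expected_level`, or until `timeout` elapses. A timeout is an
#' *outcome*, not an error; the clock advances either way.
#'
#' @param bridge a [signal_bridge()].
#' @param pin input pin number (must be configured as input).
#' @param expected_level 0 or 1.
#' @param timeout seconds to wait at most.
#' @return a one-row tibble: `signaled` (logical), `time` (virtual clock
#'   time at which the wait ended), `waited` (seconds spent waiting).
#' @export
wait_for_input <- function(bridge, pin, expected_level = 1L, timeout = 60) {
  info <- bridge$pin_info(pin)
  if (info$mode != "input") {
    stop_nanosampler(sprintf("pin %s is not configured as an input", pin), "pin_error")
  }
  now <- bridge$clock$now
  candidates <- which(!bridge$events$fired &
                        bridge$events$pin == as.integer(pin) &
                        bridge$events$level == as.integer(expected_level) &
                        bridge$events$time >= now &
                        bridge$events$time <= now + timeout)
  if (length(candidates) > 0) {
    i <- candidates[1]
    t_event <- bridge$events$time[i]
    bridge$events$fired[i] <- TRUE
    bridge$clock$advance_to(t_event)
    info$level <- as.integer(expected_level)
    assign(as.character(pin), info, envir = bridge$pins)
    bridge$log(sprintf("WAIT %s %d", pin, expected_level),
               sprintf("OK signaled at %.3f", t_event))
    tibble::tibble(signaled = TRUE, time = t_event, waited = t_event - now)
  } else {
    bridge$clock$advance(timeout)
    bridge$log(sprintf("WAIT %s %d", pin, expected_level),
               sprintf("ERR timeout after %.3f s", timeout))
    tibble::tibble(signaled = FALSE, time = now + timeout, waited = timeout)
  }
}

#' Simulated temperature deck
#'
#' First-order relaxation toward the setpoint on the virtual clock:
#' `T(t) = setpoint + (T0 - setpoint) * exp(-(t - t0) / tau)`, so the
#' current temperature approaches the setpoint monotonically. The deck is
#' used to hold plates at 4 degrees C during preparation.
#'
#' @inheritParams motion_controller
#' @param ambient starting temperature, degrees C.
#' @param tau relaxation time constant, seconds.
#' @return a `Tempdeck` R6 object with `$set_temp()` and `$read()`.
#' @export
tempdeck <- function(clock = virtual_clock(), recorder = NULL,
                     ambient = 22, tau = 120) {
  Tempdeck$new("tempdeck", clock, recorder, ambient, tau)
}

Tempdeck <- R6::R6Class("Tempdeck", inherit = SimulatedDevice,
  public = list(
    setpoint = NULL,
    tau = NULL,
    anchor_temp = NULL,
    anchor_time = NULL,
    initialize = function(device_id, clock, recorder, ambient, tau) {
      super$initialize(device_id, clock, recorder)
      self$setpoint <- ambient
      self$anchor_temp <- ambient
      self$anchor_time <- clock$now
      self$tau <- tau
    },
    read = function() {
      dt <- self$clock$now - self$anchor_time
      self$setpoint + (self$anchor_temp - self$setpoint) * exp(-dt / self$tau)
    },
    set_temp = function(setpoint) {
      self$anchor_temp <- self$read()
      self$anchor_time <- self$clock$now
      self$setpoint <- as.numeric(setpoint)
      self$log(sprintf("SETTEMP %.1f", setpoint), "OK")
      invisible(self)
    },
    handle = function(verb, args) {
      switch(verb,
        SETTEMP = { self$set_temp(as.numeric(args[1])); list(ok = TRUE) },
        "TEMP?" = list(ok = TRUE, value = sprintf("%.3f", self$read())),
        super$handle(verb, args)
      )
    },
    state = function() list(setpoint = self$setpoint, current = self$read())
  )
)

#' Move the gantry to a target with a tool offset
#'
#' Thin functional wrapper over the motion controller used by the method
#' engine: tools mounted beside the needle (e.g. the foil puncher) carry a
#' fixed XYZ offset that is added to every commanded point.
#'
#' @param motion a [motion_controller()].
#' @param target numeric XYZ, mm, machine frame.
#' @param tool_offset numeric XYZ offset of the mounted tool, mm.
#' @return a one-row arrival tibble (time, x, y, z).
#' @export
move_to <- function(motion, target, tool_offset = c(0, 0, 0)) {
  motion$move_to(target, tool_offset)
}
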