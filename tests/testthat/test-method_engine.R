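test_that("method parsing validates the step vocabulary fail-fast", {
  expect_equal(length(parse_method("")$steps), 0)

  prog <- parse_method_file(fixture_path("underfill_injection.yaml"))
  expect_s3_class(prog, "method_program")
  expect_equal(length(prog$steps), 14)
  expect_equal(prog$name, "underfill_injection")

  expect_error(parse_method("name: x\nsteps:\n  - step: aspirate\n    volume: 40"),
               class = "nanosampler_method_validation")
  # all violations reported together, with step indices
  err <- tryCatch(
    parse_method(paste(
      "name: bad", "steps:",
      "  - step: aspirate", "    volume: 40",
      "  - step: teleport", "    speed: 1",
      "  - step: valve_selector", "    port: 9",
      "  - step: wait_input", "    pin: 7",
      sep = "\n")),
    nanosampler_error = function(e) conditionMessage(e)
  )
  expect_match(err, "step 1 .*exceeds syringe capacity")
  expect_match(err, "step 2: unknown step name")
  expect_match(err, "step 3 .*port must be in 1..8")
  expect_match(err, "step 4 .*missing parameter")
})

test_that("methods round-trip through YAML serialization", {
  prog <- parse_method_file(fixture_path("underfill_injection.yaml"))
  back <- parse_method(write_method(prog))
  expect_equal(back$name, prog$name)
  expect_equal(back$steps, prog$steps)
})

test_that("execution runs steps in order against the simulated devices", {
  sys <- make_demo_system()
  prog <- method_program("two_moves", list(
    list(step = "move_to_well", labware = "sample_plate", well = "A1"),
    list(step = "move_to_well", labware = "sample_plate", well = "B2")
  ))
  tr <- execute(prog, sys)
  expect_false(tr$aborted)
  moves <- tr$entries[tr$entries$device == "motion", ]
  expect_equal(nrow(moves), 2)
  expect_equal(moves$step_index, 1:2)
  expect_true(all(diff(tr$entries$time) >= 0))
  # B2 under the identity-XY calibration sits at its grid position, z = 50
  expect_equal(unname(sys$motion$position), c(4.5, 4.5, 50))
})

test_that("uncalibrated labware is rejected before any device command", {
  sys <- make_demo_system()
  lw <- plate_384("extra_plate")
  add_labware(sys, lw)   # defined but never calibrated
  n0 <- length(sys$recorder$entries)
  pos0 <- sys$motion$position
  prog <- method_program("bad", list(
    list(step = "valve_selector", port = 3),
    list(step = "move_to_well", labware = "extra_plate", well = "A1")
  ))
  expect_error(execute(prog, sys), regexp = "extra_plate",
               class = "nanosampler_preflight_error")
  expect_equal(length(sys$recorder$entries), n0)   # nothing executed
  expect_equal(sys$motion$position, pos0)
  expect_error(execute(method_program("nolw", list(
    list(step = "move_to_well", labware = "ghost", well = "A1")
  )), sys), regexp = "ghost")
})

test_that("the syringe must be calibrated before liquid steps run", {
  sys <- sampler_system()
  prog <- method_program("asp", list(list(step = "aspirate", volume = 1)))
  expect_error(execute(prog, sys), class = "nanosampler_preflight_error")
})

test_that("pump handshake: relay pulse schedules the end-of-method signal", {
  sys <- make_demo_system()    # pump runs the 50-min default gradient
  prog <- method_program("handshake", list(
    list(step = "pulse_relay", duration = 0.5),
    list(step = "wait_input", pin = 7, level = 1, timeout = 3300),
    list(step = "comment", text = "after pump")
  ))
  t0 <- sys$clock$now
  tr <- execute(prog, sys)
  expect_false(tr$aborted)
  expect_equal(tr$totals$relay_pulses, 1L)
  expect_equal(tr$totals$signals_received, 1L)
  waits <- tr$entries[grepl("^WAIT", tr$entries$command), ]
  expect_match(waits$outcome, "signaled")
  # the signal lands 50 min after the pulse began; the next step starts then
  after <- tr$entries[tr$entries$step_index == 3, ]
  expect_equal(after$time, t0 + 50 * 60)
})

test_that("a full injection method executes with consistent accounting", {
  sys <- make_demo_system()
  prog <- parse_method_file(fixture_path("underfill_injection.yaml"))
  tr <- execute(prog, sys)
  expect_false(tr$aborted)
  g <- glance(tr)
  expect_equal(g$aspirated_ul, 4)
  expect_equal(g$dispensed_ul, 4)
  expect_equal(g$relay_pulses, 1L)
  expect_equal(g$signals_received, 1L)
  # the punched well is no longer sealed
  expect_false(sys$state$sealed[["sample_plate"]][2, 2])
  expect_true(sys$state$sealed[["sample_plate"]][1, 1])
})

test_that("queues run first-in-first-out and halt on failure", {
  sys <- make_demo_system()
  inj <- function(name) {
    prog <- parse_method_file(fixture_path("underfill_injection.yaml"))
    prog$name <- name
    prog
  }
  traces <- run_queue(queue_methods(list(inj("a"), inj("b"), inj("c"))), sys)
  expect_equal(names(traces), c("a", "b", "c"))
  expect_true(all(vapply(traces, function(t) t$totals$relay_pulses == 1L, logical(1))))
  expect_equal(attr(traces, "unrun"), character(0))

  sys2 <- make_demo_system()
  failing <- method_program("fails", list(
    list(step = "aspirate", volume = 20),
    list(step = "aspirate", volume = 20)   # second aspirate overruns the syringe
  ))
  out <- run_queue(queue_methods(list(failing, inj("after"))), sys2)
  expect_true(out$fails$aborted)
  expect_match(out$fails$error, "syringe fill")
  expect_equal(attr(out, "unrun"), "after")
  expect_false("after" %in% names(out))

  expect_equal(length(run_queue(queue_methods(), make_demo_system())), 0)
})

test_that("execution is deterministic given the scripted events", {
  run <- function() {
    sys <- make_demo_system()
    tr <- execute(parse_method_file(fixture_path("underfill_injection.yaml")), sys)
    tr$entries
  }
  expect_identical(run(), run())
})

test_that("the bundled gradient matches the pump program", {
  prof <- lc_gradient_default()
  expect_equal(percent_b(prof, 0), 1)     # initial %B
  expect_equal(percent_b(prof, 21), 25)   # end of the 20-min elution ramp
  expect_equal(percent_b(prof, 11), 15)   # midpoint of the 5 -> 25% ramp
  g <- glance(prof)
  expect_equal(g$duration_min, 50)
  expect_equal(g$start_percent_b, 1)
  expect_equal(g$end_percent_b, 1)
  expect_equal(g$max_percent_b, 75)
  expect_error(percent_b(prof, 51), class = "nanosampler_range_error")
  expect_error(percent_b(prof, -1), class = "nanosampler_range_error")
  expect_error(gradient_profile(c(0, 0), c(1, 5)), class = "nanosampler_gradient_error")
  expect_error(gradient_profile(c(0, 1), c(1, 105)), class = "nanosampler_gradient_error")
})
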