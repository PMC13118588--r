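test_that("LOAD and INJECT positions expose the documented paths", {
  net <- fluid_network()
  # LOAD: needle -> loop -> selector link -> transfer -> syringe line
  p <- active_path(net, "needle", "syringe", selector = 6, two_position = "A")
  expect_equal(p$label, c("needle", "loop", "transfer line", "syringe line"))
  # LOAD: pump flows straight to the column, bypassing the loop
  bypass <- active_path(net, "pump", "column", selector = 6, two_position = "A")
  expect_false(any(bypass$label == "loop"))
  # INJECT: pump -> loop -> column (the loop online with pump and column)
  inj <- active_path(net, "pump", "column", selector = 6, two_position = "B")
  expect_true(any(inj$label == "loop"))
  # LOAD: pump and needle are disconnected
  expect_null(active_path(net, "pump", "needle", selector = 6, two_position = "A"))
  # solvent and waste reachable from the syringe through the selector
  expect_true(!is.null(active_path(net, "syringe", "solventA", selector = 3)))
  expect_true(!is.null(active_path(net, "syringe", "waste", selector = 1)))
  # unused selector ports are dead ends
  expect_null(active_path(net, "syringe", "needle", selector = 4, two_position = "A"))
  expect_error(active_path(net, "nozzle", "syringe"), class = "nanosampler_network_error")
})

test_that("plug advection preserves widths and spacing", {
  s <- plug_state(tibble::tibble(label = "sample", upstream = 0.5, downstream = 0))
  s2 <- advance_plugs(s, 3.5, "aspirate")
  expect_equal(s2$upstream, 4.0)
  expect_equal(s2$downstream, 3.5)
  expect_identical(tibble::as_tibble(advance_plugs(s2, 0, "aspirate"))[1:3],
                   tibble::as_tibble(s2)[1:3])

  two <- plug_state(tibble::tibble(label = c("a", "b"),
                                   upstream = c(0.5, 2.0), downstream = c(0, 1.2)))
  moved <- advance_plugs(two, 1.7, "aspirate")
  expect_equal(moved$downstream[2] - moved$upstream[1],
               two$downstream[2] - two$upstream[1])
  expect_error(advance_plugs(two, -1, "aspirate"), class = "nanosampler_plug_error")
})

test_that("plug widths are invariant under random advection sequences", {
  withr::local_seed(21)
  for (rep in 1:20) {
    s <- plug_state(tibble::tibble(label = "sample", upstream = 1.3, downstream = 0.8))
    pos <- c(0.8, 1.3)
    for (step in 1:30) {
      vol <- runif(1, 0, 2)
      # choose a direction that keeps the plug strictly inside a 30 uL path
      dir <- if (pos[1] - vol < 0) "aspirate"
             else if (pos[2] + vol > 30) "dispense"
             else sample(c("aspirate", "dispense"), 1)
      shift <- if (dir == "aspirate") vol else -vol
      pos <- pos + shift
      s <- advance_plugs(s, vol, dir, path_volume = 30)
    }
    expect_equal(s$upstream - s$downstream, 0.5, tolerance = 1e-9)
    expect_equal(c(s$downstream, s$upstream), pos, tolerance = 1e-9)
  }
})

test_that("underfill and overfill plans reproduce the loop interval arithmetic", {
  net <- fluid_network()  # D = 3.2 uL, loop = 1.021 uL
  under <- plan_injection(net, "underfill", 500, 3500)
  expect_true(under$valid)
  expect_equal(unname(under$plug_interval), c(4.0, 3.5))
  expect_equal(unname(under$loop_interval),
               c(3.2 + capillary_volume(capillary_spec(13, 100)), 3.2))
  expect_equal(under$injected_volume_nl, 500)

  over <- plan_injection(net, "overfill", 1700, 3000)
  expect_true(over$valid)
  expect_equal(unname(over$plug_interval), c(4.7, 3.0))
  expect_equal(over$injected_volume_nl, net$loop_volume_ul * 1000)

  # impossible geometries yield invalid plans with diagnostics, not errors
  big <- plan_injection(net, "underfill", 1500, 3500)
  expect_false(big$valid)
  expect_match(big$diagnostic, "exceeds loop capacity")
  short_chase <- plan_injection(net, "underfill", 500, 1000)
  expect_false(short_chase$valid)
  expect_match(short_chase$diagnostic, "dead volume")
  expect_error(plan_injection(net, "underfill", 0, 3500),
               class = "nanosampler_plan_error")
})

test_that("underfill validity is contiguous in chase volume", {
  net <- fluid_network()
  chases <- seq(100, 6000, by = 25)
  valid <- vapply(chases, function(ch)
    plan_injection(net, "underfill", 500, ch)$valid, logical(1))
  runs <- rle(valid)
  expect_equal(sum(runs$values), 1)  # exactly one contiguous valid interval
  # and that interval is [D, D + V_loop - sample] in chase space
  expect_equal(range(chases[valid]), c(3200, 3700), tolerance = 25)
})

test_that("injected volume never exceeds the loop volume", {
  net <- fluid_network()
  withr::local_seed(33)
  for (i in 1:10000) {
    plan <- plan_injection(net,
                           sample(c("underfill", "overfill"), 1),
                           runif(1, 1, 5000), runif(1, 1, 6000))
    expect_lte(plan$injected_volume_nl, net$loop_volume_ul * 1000 + 1e-9)
  }
})

test_that("injected mass follows volume x concentration", {
  net <- fluid_network()
  under <- plan_injection(net, "underfill", 500, 3500)
  expect_equal(injected_mass(under, 20), 10)           # 10 ng
  nominal <- fluid_network(loop_volume_ul = 1)
  over <- plan_injection(nominal, "overfill", 1700, 3000)
  expect_equal(injected_mass(over, 0.25), 0.25)        # 250 pg
  expect_equal(injected_mass(under, 0), 0)
  bad <- plan_injection(net, "underfill", 500, 1000)
  expect_error(injected_mass(bad, 20), class = "nanosampler_plan_error")
})

test_that("volume is conserved between plunger displacement and path volume", {
  sys <- make_demo_system()
  withr::local_seed(17)
  profile <- calibrate_syringe(TRUE, 60, 0, 10)
  net_aspirated <- 0
  fill <- 0
  steps <- list()
  for (i in 1:40) {
    vol <- runif(1, 0, 3)
    dir <- if (fill + vol > 25) "dispense"
           else if (fill - vol < 0) "aspirate"
           else sample(c("aspirate", "dispense"), 1)
    vol <- min(vol, if (dir == "dispense") fill else 25 - fill)
    if (vol <= 0) next
    fill <- fill + ifelse(dir == "aspirate", vol, -vol)
    steps <- c(steps, list(list(step = dir, volume = vol)))
  }
  prog <- method_program("conservation", steps)
  tr <- execute(prog, sys)
  expect_false(tr$aborted)
  net_ul <- tr$totals$aspirated_ul - tr$totals$dispensed_ul
  plunger_travel <- sys$motion$plunger - sys$motion$limits$p[1]
  expect_equal(plunger_travel * profile$units_per_mm, net_ul, tolerance = 1e-9)
  expect_equal(sys$state$syringe_fill_ul, net_ul, tolerance = 1e-9)
})

test_that("the flush routine clears plugs and reports their volume", {
  net <- fluid_network()
  expect_warning(flush_plan(net, 0), class = "nanosampler_incomplete_flush")
  expect_warning(flush_plan(net, 0.5), class = "nanosampler_incomplete_flush")

  sys <- make_demo_system()
  # leave a residual 0.8 uL plug sitting in the loop region
  sys$state$plugs <- plug_state(tibble::tibble(label = "residual",
                                               upstream = 4.0, downstream = 3.2))
  tr <- execute(flush_plan(sys$network, 25), sys)
  expect_false(tr$aborted)
  expect_equal(tr$totals$loop_volume_ul, 25)
  expect_equal(nrow(sys$state$plugs), 0)
  expect_equal(tr$totals$plug_volume_expelled_ul, 0.8, tolerance = 1e-9)
})
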