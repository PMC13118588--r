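# Shared fixtures: a fully calibrated simulated system and random affine
# deck deformations.

demo_corners <- function(labware) {
  lapply(list(well_address(1, 1),
              well_address(1, labware$columns),
              well_address(labware$rows, 1)), identity)
}

# measured machine coordinates of the three corners under an affine map:
# xy -> A %*% xy + b, z = plane(gx, gy)
measure_corners <- function(labware, A = diag(2), b = c(0, 0),
                            plane = c(0, 0, 50), wells = demo_corners(labware)) {
  t(vapply(wells, function(w) {
    g <- grid_position(labware, w)
    xy <- as.numeric(A %*% g + b)
    c(xy, sum(plane * c(g, 1)))
  }, numeric(3)))
}

random_affine <- function() {
  repeat {
    A <- matrix(stats::rnorm(4, sd = 0.3), 2, 2) + diag(2)
    if (abs(det(A)) > 0.2) break
  }
  list(A = A, b = stats::rnorm(2, sd = 20), plane = c(stats::rnorm(2, sd = 0.05), 50))
}

make_demo_system <- function(network = fluid_network(), with_pump = TRUE) {
  sys <- sampler_system(network = network)
  if (with_pump) attach_pump(sys, lc_gradient_default())
  for (nm in c("sample_plate", "solvent_reservoir")) {
    lw <- plate_384(nm)
    add_labware(sys, lw, sealed = TRUE)
    measured <- measure_corners(lw)
    register_calibration(sys$registry,
                         fit_plate_calibration(lw, measured, demo_corners(lw)))
  }
  sys$motion$home("ALL")
  set_syringe(sys, calibrate_syringe(TRUE, 60, 0, 10))
  sys
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "nanosampler")
}
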