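#' Syringe plunger profile
#'
#' Maps dispensed/aspirated volume to linear plunger travel for a gastight
#' syringe driven by the converted pipette motor. The barrel is cylindrical,
#' so the map is linear: `units_per_mm = nominal_volume / |max - min|`.
#' Profiles are created by [calibrate_syringe()] after homing; they are
#' deliberately never persisted — syringes must be recalibrated whenever the
#' software restarts to guarantee the proper range of motion.
#'
#' @param nominal_volume syringe capacity in uL (25 for the gastight
#'   syringe used on the reference build).
#' @param max_position plunger position, mm, fully retracted.
#' @param min_position plunger position, mm, fully depressed.
#' @param reference_position preferred resting position, mm, within
#'   `[min_position, max_position]`.
#' @return a `syringe_profile` object.
#' @export
syringe_profile <- function(nominal_volume = 25, max_position = 60,
                            min_position = 0, reference_position = min_position) {
  if (max_position == min_position) {
    stop_nanosampler("degenerate stroke: max_position equals min_position", "syringe_error")
  }
  if (reference_position < min(min_position, max_position) ||
      reference_position > max(min_position, max_position)) {
    stop_nanosampler("reference position must lie within [min, max]", "syringe_error")
  }
  if (nominal_volume <= 0) {
    stop_nanosampler("nominal volume must be positive", "syringe_error")
  }
  structure(
    list(
      nominal_volume = as.numeric(nominal_volume),
      max_position = as.numeric(max_position),
      min_position = as.numeric(min_position),
      reference_position = as.numeric(reference_position),
      units_per_mm = nominal_volume / abs(max_position - min_position)
    ),
    class = "syringe_profile"
  )
}

#' @export
print.syringe_profile <- function(x, ...) {
  cat(sprintf("<syringe_profile> %g uL over %g mm stroke (%.6g uL/mm)\n",
              x$nominal_volume, abs(x$max_position - x$min_position), x$units_per_mm))
  invisible(x)
}

#' Calibrate a syringe after homing
#'
#' Syringe calibration consists of homing the plunger motor and then
#' recording a maximum and minimum plunger position plus a preferred
#' reference position. Positions offered before homing are rejected.
#'
#' @param homed logical: has the plunger axis been homed this session? Pass
#'   a [motion_controller()] to read its homed flag instead.
#' @inheritParams syringe_profile
#' @return a [syringe_profile()].
#' @export
calibrate_syringe <- function(homed, max_position, min_position,
                              reference_position, nominal_volume = 25) {
  if (inherits(homed, "R6") && !is.null(homed$is_homed)) {
    homed <- homed$is_homed("P")
  }
  if (!isTRUE(homed)) {
    stop_nanosampler("syringe positions cannot be set before the plunger motor is homed",
                     "ordering_violation")
  }
  syringe_profile(nominal_volume, max_position, min_position, reference_position)
}

#' Convert a target volume to plunger travel
#'
#' @param profile a [syringe_profile()].
#' @param volume target volume; numeric uL or a unit string (`"500 nL"`).
#' @return plunger travel in mm.
#' @examples
#' p <- syringe_profile(25, max_position = 60, min_position = 0)
#' travel_for_volume(p, 5)        # 12 mm
#' @export
travel_for_volume <- function(profile, volume) {
  volume <- as_microliters(volume)
  if (any(volume < 0) || any(volume > profile$nominal_volume)) {
    stop_nanosampler(
      sprintf("volume %g uL outside syringe range [0, %g] uL",
              volume[volume < 0 | volume > profile$nominal_volume][1],
              profile$nominal_volume),
      "capacity_error"
    )
  }
  volume / profile$units_per_mm
}

#' @rdname travel_for_volume
#' @param travel plunger travel in mm.
#' @export
volume_for_travel <- function(profile, travel) {
  stroke <- abs(profile$max_position - profile$min_position)
  if (any(travel < 0) || any(travel > stroke)) {
    stop_nanosampler("travel outside plunger stroke", "capacity_error")
  }
  travel * profile$units_per_mm
}

#' Piecewise conversion table for driving the stock pipette software
#'
#' The unmodified robot software exposes pipette volumes, not plunger
#' distances; it converts commanded volumes to travel through vendor
#' piecewise functions. To drive a mounted syringe through that stock
#' path, a target syringe volume is converted to linear distance
#' ([travel_for_volume()]) and the distance is then converted back into the
#' equivalent commanded stock-software volume through this table
#' ([stock_volume_for_travel()]). The vendor coefficients are not public;
#' the table is user-supplied configuration, monotone in both coordinates
#' with its first breakpoint at (0, 0), interpolated linearly between
#' breakpoints.
#'
#' @param stock_volume commanded stock-software volumes, uL, strictly
#'   increasing, starting at 0.
#' @param travel plunger travel, mm, strictly increasing, starting at 0.
#' @return a `piecewise_conversion` object.
#' @examples
#' tab <- piecewise_conversion(stock_volume = c(0, 5, 10), travel = c(0, 5, 20))
#' stock_volume_for_travel(tab, 12.5)   # 7.5 uL
#' @export
piecewise_conversion <- function(stock_volume, travel) {
  stock_volume <- as.numeric(stock_volume)
  travel <- as.numeric(travel)
  if (length(stock_volume) != length(travel) || length(travel) < 2) {
    stop_nanosampler("need matching vectors of at least two breakpoints", "table_error")
  }
  if (stock_volume[1] != 0 || travel[1] != 0) {
    stop_nanosampler("first breakpoint must be (0, 0)", "table_error")
  }
  if (any(diff(stock_volume) <= 0) || any(diff(travel) <= 0)) {
    stop_nanosampler("breakpoints must be strictly increasing in both coordinates",
                     "table_error")
  }
  structure(
    list(breakpoints = tibble::tibble(stock_volume = stock_volume, travel = travel)),
    class = "piecewise_conversion"
  )
}

#' @rdname piecewise_conversion
#' @param table a `piecewise_conversion`.
#' @export
travel_for_stock_volume <- function(table, stock_volume) {
  bp <- table$breakpoints
  if (any(stock_volume < min(bp$stock_volume)) || any(stock_volume > max(bp$stock_volume))) {
    stop_nanosampler("stock volume outside conversion-table range", "range_error")
  }
  stats::approx(bp$stock_volume, bp$travel, xout = stock_volume, ties = "ordered")$y
}

#' @rdname piecewise_conversion
#' @param travel plunger travel in mm.
#' @export
stock_volume_for_travel <- function(table, travel) {
  bp <- table$breakpoints
  if (any(travel < min(bp$travel)) || any(travel > max(bp$travel))) {
    stop_nanosampler("travel outside conversion-table range", "range_error")
  }
  stats::approx(bp$travel, bp$stock_volume, xout = travel, ties = "ordered")$y
}

#' Fused silica capillary specification and volume
#'
#' Capillary internal volumes drive all of the loop and dead-volume
#' accounting: `volume = pi * (id / 2)^2 * length`. The reference build's
#' sample loop is 13 cm of 100 um i.d. capillary, i.e. 1.02 uL — the
#' "1 uL sample loop".
#'
#' @param length_cm capillary length in cm.
#' @param id_um inner diameter in um.
#' @param label optional label.
#' @return `capillary_spec()` returns a spec; `capillary_volume()` its
#'   internal volume in uL.
#' @examples
#' capillary_volume(capillary_spec(13, 100))   # ~1.02 uL
#' @export
capillary_spec <- function(length_cm, id_um, label = "") {
  if (length_cm <= 0 || id_um <= 0) {
    stop_nanosampler("capillary length and inner diameter must be positive", "capillary_error")
  }
  structure(
    list(length_cm = as.numeric(length_cm), id_um = as.numeric(id_um),
         label = as.character(label)),
    class = "capillary_spec"
  )
}

#' @rdname capillary_spec
#' @param spec a `capillary_spec`.
#' @export
capillary_volume <- function(spec) {
  radius_cm <- spec$id_um / 2 * 1e-4
  # cm^3 == mL; 1 mL = 1000 uL
  pi * radius_cm^2 * spec$length_cm * 1000
}
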