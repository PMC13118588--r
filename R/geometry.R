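#' Define a piece of labware with an evenly spaced well grid
#'
#' Well-plate calibration in this package assumes all wells are evenly
#' spaced, so nominal well positions form a regular grid by construction:
#' local X grows with column index, local Y with row index, and well A1 is
#' the grid origin.
#'
#' @param name labware name (unique within a deck).
#' @param rows,columns grid size (e.g. 16 x 24 for a 384-well plate).
#' @param row_pitch,column_pitch well-to-well spacing in mm (4.5 mm for a
#'   standard 384-well plate).
#' @param well_depth well depth in mm.
#' @param well_volume_capacity working volume per well in uL.
#' @param slot deck-slot identifier.
#' @return a `labware_definition` object.
#' @examples
#' plate_384(slot = "3")
#' @export
labware_definition <- function(name, rows, columns, row_pitch, column_pitch,
                               well_depth = 10, well_volume_capacity = 100,
                               slot = "1") {
  if (!(rows >= 1 && columns >= 1)) {
    stop_nanosampler("labware must have at least one row and one column", "labware_error")
  }
  if (!(row_pitch > 0 && column_pitch > 0)) {
    stop_nanosampler("well pitches must be positive", "labware_error")
  }
  structure(
    list(
      name = as.character(name),
      rows = as.integer(rows), columns = as.integer(columns),
      row_pitch = as.numeric(row_pitch), column_pitch = as.numeric(column_pitch),
      well_depth = as.numeric(well_depth),
      well_volume_capacity = as.numeric(well_volume_capacity),
      slot = as.character(slot)
    ),
    class = "labware_definition"
  )
}

#' @rdname labware_definition
#' @export
plate_384 <- function(name = "plate_384", slot = "1") {
  labware_definition(name, rows = 16, columns = 24,
                     row_pitch = 4.5, column_pitch = 4.5,
                     well_depth = 11.4, well_volume_capacity = 112,
                     slot = slot)
}

#' @export
print.labware_definition <- function(x, ...) {
  cat(sprintf("<labware_definition> %s: %d x %d wells, pitch %g x %g mm, slot %s\n",
              x$name, x$rows, x$columns, x$row_pitch, x$column_pitch, x$slot))
  invisible(x)
}

#' Well addresses
#'
#' Wells are addressed by row letter (A = first row) and 1-based column
#' number, the usual microplate convention ("B2", "P24", ...).
#'
#' @param x a character address like `"B2"`, or a row number when `column`
#'   is given.
#' @param column 1-based column number (when `x` is the row number).
#' @return a `well_address` with fields `row` and `column` (both 1-based).
#' @examples
#' well_address("P24")
#' well_address(16, 24)
#' @export
well_address <- function(x, column = NULL) {
  if (inherits(x, "well_address")) return(x)
  if (is.character(x) && is.null(column)) {
    m <- regmatches(x, regexec("^([A-Za-z]+)([0-9]+)$", x))[[1]]
    if (length(m) != 3) {
      stop_nanosampler(sprintf("malformed well address %s", dQuote(x)), "address_error")
    }
    row <- row_letters_to_index(toupper(m[2]))
    column <- as.integer(m[3])
  } else {
    row <- as.integer(x)
    column <- as.integer(column)
  }
  if (is.na(row) || is.na(column) || row < 1 || column < 1) {
    stop_nanosampler("well address must have row >= A and column >= 1", "address_error")
  }
  structure(list(row = row, column = column), class = "well_address")
}

row_letters_to_index <- function(s) {
  # bijective base-26: A=1 ... Z=26, AA=27, ...
  chars <- utf8ToInt(s) - utf8ToInt("A") + 1L
  Reduce(function(acc, d) acc * 26L + d, chars, accumulate = FALSE)
}

index_to_row_letters <- function(i) {
  out <- character(0)
  while (i > 0) {
    r <- (i - 1L) %% 26L
    out <- c(intToUtf8(utf8ToInt("A") + r), out)
    i <- (i - 1L) %/% 26L
  }
  paste(out, collapse = "")
}

#' @export
format.well_address <- function(x, ...) {
  paste0(index_to_row_letters(x$row), x$column)
}

#' @export
print.well_address <- function(x, ...) {
  cat("<well>", format(x), "\n")
  invisible(x)
}

check_address_bounds <- function(labware, well) {
  well <- well_address(well)
  if (well$row > labware$rows || well$column > labware$columns) {
    stop_nanosampler(
      sprintf("well %s is outside labware %s (%d rows x %d columns)",
              format(well), dQuote(labware$name), labware$rows, labware$columns),
      "address_error"
    )
  }
  well
}

#' Nominal grid position of a well
#'
#' Local coordinates of a well on an evenly spaced plate, in mm from the A1
#' origin: X = (column - 1) * column_pitch, Y = (row - 1) * row_pitch.
#'
#' @param labware a [labware_definition()].
#' @param well a well address (string or [well_address()]).
#' @return named numeric vector `c(x =, y =)` in mm.
#' @examples
#' grid_position(plate_384(), "B2")
#' @export
grid_position <- function(labware, well) {
  well <- check_address_bounds(labware, well)
  c(x = (well$column - 1) * labware$column_pitch,
    y = (well$row - 1) * labware$row_pitch)
}

default_corner_wells <- function(labware) {
  # calibrate A1, A<last column>, <last row>1; verify <last row><last column>
  list(
    well_address(1, 1),
    well_address(1, labware$columns),
    well_address(labware$rows, 1)
  )
}

fourth_corner_well <- function(labware) {
  well_address(labware$rows, labware$columns)
}

#' Fit a three-corner plate calibration
#'
#' Three measured corner wells exactly determine an affine map from the
#' plate's nominal grid to machine coordinates: a 2x2 linear part plus a
#' translation in XY, and a plane through the three measured Z values
#' (supporting tilted labware). The calibration is an exact interpolant:
#' applying it to the three calibrated corners reproduces their measured
#' machine coordinates to numerical precision.
#'
#' @param labware a [labware_definition()].
#' @param corner_wells list of three well addresses; defaults to A1,
#'   A(last column) and (last row)1 so that the fourth corner
#'   (last row)(last column) is available for verification.
#' @param measured 3 x 3 numeric matrix of measured machine coordinates
#'   (rows = corners in the same order, columns = X, Y, Z in mm).
#' @param residual_tolerance acceptance tolerance (mm) for the fourth-corner
#'   verification; default 0.5 mm.
#' @return a `plate_calibration` object.
#' @seealso [predict_well()], [verify_fourth_corner()]
#' @export
fit_plate_calibration <- function(labware, measured,
                                  corner_wells = default_corner_wells(labware),
                                  residual_tolerance = 0.5) {
  stopifnot(length(corner_wells) == 3)
  corner_wells <- lapply(corner_wells, function(w) check_address_bounds(labware, w))
  measured <- as.matrix(measured)
  if (!is.numeric(measured) || !all(dim(measured) == c(3, 3))) {
    stop_nanosampler("measured must be a 3 x 3 numeric matrix (corners x XYZ)", "calibration_error")
  }
  grid <- t(vapply(corner_wells, function(w) grid_position(labware, w), numeric(2)))
  # non-collinearity in grid space: area of the corner triangle
  area2 <- det(rbind(grid[2, ] - grid[1, ], grid[3, ] - grid[1, ]))
  if (abs(area2) < 1e-9) {
    stop_nanosampler("corner wells are collinear or duplicated; cannot fit an affine map",
                     "degenerate_geometry")
  }
  design <- cbind(grid, 1)            # 3 x 3: [gx gy 1]
  coef_xy <- solve(design, measured[, 1:2, drop = FALSE])  # 3 x 2
  plane <- solve(design, measured[, 3])                    # z = a gx + b gy + c
  linear_part <- t(coef_xy[1:2, , drop = FALSE])           # 2 x 2, machine <- grid
  dimnames(linear_part) <- NULL
  if (abs(det(linear_part)) < 1e-9) {
    stop_nanosampler("fitted linear part is singular; measured corners are degenerate",
                     "degenerate_geometry")
  }
  structure(
    list(
      labware_name = labware$name,
      slot = labware$slot,
      linear_part = linear_part,
      translation = as.numeric(coef_xy[3, ]),
      plane = as.numeric(plane),
      residual_tolerance = as.numeric(residual_tolerance),
      corner_wells = vapply(corner_wells, format, character(1)),
      measured = unname(measured),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    ),
    class = "plate_calibration"
  )
}

#' @export
print.plate_calibration <- function(x, ...) {
  cat(sprintf("<plate_calibration> %s (slot %s)\n", x$labware_name, x$slot))
  cat("  corners:", paste(x$corner_wells, collapse = ", "), "\n")
  cat(sprintf("  |det| = %.6g, translation = (%.3f, %.3f) mm\n",
              abs(det(x$linear_part)), x$translation[1], x$translation[2]))
  invisible(x)
}

#' Predict the machine position of a well under a calibration
#'
#' Applies the fitted affine map to the well's nominal grid position. For
#' the un-calibrated fourth corner of a rectangular corner set this equals
#' the parallelogram completion measured(A) + measured(C) - measured(B) of
#' the three calibrated corners.
#'
#' @param calibration a `plate_calibration`.
#' @param labware the [labware_definition()] the calibration refers to.
#' @param well well address.
#' @return named numeric `c(x =, y =, z =)` machine coordinates in mm.
#' @export
predict_well <- function(calibration, labware, well) {
  well <- check_address_bounds(labware, well)
  g <- grid_position(labware, well)
  xy <- as.numeric(calibration$linear_part %*% g + calibration$translation)
  z <- sum(calibration$plane * c(g, 1))
  c(x = xy[1], y = xy[2], z = z)
}

#' Verify a calibration at the fourth corner
#'
#' The calibration workflow measures three corner wells and then drives the
#' needle to the fourth corner to let the user accept the calibration or
#' recalibrate. This function performs the numerical half of that check:
#' the residual between the predicted fourth-corner position and its
#' measured machine position.
#'
#' @inheritParams predict_well
#' @param measured_fourth measured machine XYZ (mm) at the fourth corner.
#' @return a one-row tibble with the well, predicted and measured
#'   coordinates, the XY(Z) residual in mm and whether it is within the
#'   calibration's `residual_tolerance`.
#' @export
verify_fourth_corner <- function(calibration, labware, measured_fourth,
                                 well = fourth_corner_well(labware)) {
  pred <- predict_well(calibration, labware, well)
  measured_fourth <- as.numeric(measured_fourth)
  resid <- sqrt(sum((pred - measured_fourth)^2))
  tibble::tibble(
    labware = calibration$labware_name,
    well = format(well_address(well)),
    predicted_x = pred[["x"]], predicted_y = pred[["y"]], predicted_z = pred[["z"]],
    measured_x = measured_fourth[1], measured_y = measured_fourth[2],
    measured_z = measured_fourth[3],
    residual_mm = resid,
    accepted = resid <= calibration$residual_tolerance
  )
}

#' Calibration registry
#'
#' The execution engine keeps calibrations in a registry that starts empty
#' on every software restart; calibrations appear only after an explicit
#' fit or an explicit load from a saved calibration file.
#'
#' @return `calibration_registry()` returns an empty registry.
#' @export
calibration_registry <- function() {
  structure(list(store = new.env(parent = emptyenv())), class = "calibration_registry")
}

#' @rdname calibration_registry
#' @param registry a calibration registry.
#' @param calibration a `plate_calibration` to add (keyed by labware name).
#' @export
register_calibration <- function(registry, calibration) {
  stopifnot(inherits(registry, "calibration_registry"),
            inherits(calibration, "plate_calibration"))
  assign(calibration$labware_name, calibration, envir = registry$store)
  invisible(registry)
}

#' @rdname calibration_registry
#' @param labware_name labware name to look up.
#' @export
get_calibration <- function(registry, labware_name) {
  if (!exists(labware_name, envir = registry$store, inherits = FALSE)) {
    return(NULL)
  }
  get(labware_name, envir = registry$store, inherits = FALSE)
}

#' @rdname calibration_registry
#' @export
list_calibrations <- function(registry) {
  sort(ls(registry$store))
}

#' Save and load calibration files
#'
#' Calibrations are persisted as JSON, one record per labware, with numeric
#' fields serialized at 17 significant digits so that a save/load round
#' trip reproduces every field bit-for-bit at double precision. Saved
#' files must be re-loaded whenever the software is restarted: registries
#' always start empty.
#'
#' @param registry a calibration registry (or list of `plate_calibration`s).
#' @param path file path.
#' @return `load_calibrations()` returns a fresh registry populated from
#'   the file (an empty file yields an empty registry).
#' @export
save_calibrations <- function(registry, path) {
  cals <- if (inherits(registry, "calibration_registry")) {
    lapply(list_calibrations(registry), get_calibration, registry = registry)
  } else {
    registry
  }
  records <- lapply(cals, function(cal) {
    list(
      labware_name = cal$labware_name,
      slot = cal$slot,
      corner_wells = cal$corner_wells,
      measured = cal$measured,
      linear_part = cal$linear_part,
      translation = cal$translation,
      plane = cal$plane,
      residual_tolerance = cal$residual_tolerance,
      timestamp = cal$timestamp
    )
  })
  json <- jsonlite::toJSON(records, digits = I(17), auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_calibrations
#' @export
load_calibrations <- function(path) {
  registry <- calibration_registry()
  if (!file.exists(path)) {
    stop_nanosampler(sprintf("calibration file %s does not exist", dQuote(path)), "io_error")
  }
  raw <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!nzchar(trimws(raw))) {
    return(registry)
  }
  records <- tryCatch(
    jsonlite::fromJSON(raw, simplifyVector = FALSE),
    error = function(e) {
      stop_nanosampler(
        sprintf("malformed calibration file %s: %s", dQuote(path), conditionMessage(e)),
        "parse_error"
      )
    }
  )
  required <- c("labware_name", "slot", "corner_wells", "measured",
                "linear_part", "translation", "plane", "residual_tolerance")
  for (i in seq_along(records)) {
    rec <- records[[i]]
    missing <- setdiff(required, names(rec))
    if (length(missing) > 0) {
      stop_nanosampler(
        sprintf("calibration record %d is missing field(s): %s",
                i, paste(missing, collapse = ", ")),
        "parse_error"
      )
    }
    cal <- structure(
      list(
        labware_name = rec$labware_name,
        slot = rec$slot,
        linear_part = matrix(unlist(rec$linear_part), nrow = 2, byrow = TRUE),
        translation = as.numeric(unlist(rec$translation)),
        plane = as.numeric(unlist(rec$plane)),
        residual_tolerance = as.numeric(rec$residual_tolerance),
        corner_wells = as.character(unlist(rec$corner_wells)),
        measured = matrix(unlist(rec$measured), nrow = 3, byrow = TRUE),
        timestamp = rec$timestamp %||% NA_character_
      ),
      class = "plate_calibration"
    )
    register_calibration(registry, cal)
  }
  registry
}

`%||%` <- function(a, b) if (is.null(a)) b else a
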