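#' Fluorescein dilution assay design
#'
#' Sub-microliter dispensing is verified fluorimetrically: aliquots of
#' sodium fluorescein stock are dispensed into wells prefilled with 20 uL
#' of buffer and read against hand-pipetted calibration standards. The
#' default design pairs dispense volumes of 500, 100, 50, 20, 10 and 5 nL
#' with stocks of 0.2, 1, 2, 5, 10 and 20 mM — every pair targets the
#' same nominal final concentration of 5 uM — alongside standards at 3,
#' 4, 5, 6 and 7 uM with five replicates each.
#'
#' @param dispense_sets tibble with columns `volume_nl`, `stock_mm`,
#'   `replicates`.
#' @param prefill_ul well prefill volume, uL.
#' @param standards tibble with columns `concentration_um`, `replicates`.
#' @param target_um the design's common nominal final concentration; a
#'   dispense set whose nominal concentration differs triggers a warning.
#' @return an `assay_design` object.
#' @export
assay_design <- function(
    dispense_sets = tibble::tibble(
      volume_nl = c(500, 100, 50, 20, 10, 5),
      stock_mm = c(0.2, 1, 2, 5, 10, 20),
      replicates = 5L
    ),
    prefill_ul = 20,
    standards = tibble::tibble(concentration_um = 3:7, replicates = 5L),
    target_um = 5) {
  dispense_sets <- tibble::as_tibble(dispense_sets)
  standards <- tibble::as_tibble(standards)
  if (any(dispense_sets$volume_nl <= 0) || any(dispense_sets$stock_mm <= 0) ||
      prefill_ul <= 0 || any(standards$concentration_um <= 0)) {
    stop_nanosampler("all design volumes and concentrations must be positive",
                     "design_error")
  }
  nominal <- nominal_final_concentration(dispense_sets$volume_nl,
                                         dispense_sets$stock_mm, prefill_ul)
  if (any(abs(nominal - target_um) > 1e-9)) {
    warn_nanosampler(
      sprintf("dispense set(s) %s deviate from the %g uM design target",
              paste(which(abs(nominal - target_um) > 1e-9), collapse = ", "),
              target_um),
      "design_target"
    )
  }
  structure(
    list(dispense_sets = dispense_sets, prefill_ul = prefill_ul,
         standards = standards, target_um = target_um),
    class = "assay_design"
  )
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf("<assay_design> %d dispense sets into %g uL prefill, %d standards\n",
              nrow(x$dispense_sets), x$prefill_ul, nrow(x$standards)))
  invisible(x)
}

#' Nominal final concentration of a dispense design point
#'
#' Design-ratio dilution convention: `C_final = C_stock * V_dispense /
#' V_prefill`, the convention the printed design targets satisfy (500 nL
#' of 0.2 mM into 20 uL -> 5 uM, ... , 5 nL of 20 mM into 20 uL -> 5 uM).
#' The *exact* convention divides by `V_prefill + V_dispense` instead;
#' both conventions agree to within 2.5% at the largest design volume and
#' the exact one is used when estimating dispensed volumes
#' ([estimate_dispensed_volume()]).
#'
#' @param volume_nl dispensed volume, nL.
#' @param stock_mm stock concentration, mM.
#' @param prefill_ul well prefill volume, uL.
#' @param exact use the exact dilution denominator `prefill + dispense`.
#' @return final concentration in uM (vectorized).
#' @examples
#' nominal_final_concentration(5, 20, 20)   # 5 uM
#' @export
nominal_final_concentration <- function(volume_nl, stock_mm, prefill_ul = 20,
                                        exact = FALSE) {
  if (any(volume_nl < 0) || any(stock_mm <= 0) || any(prefill_ul <= 0)) {
    stop_nanosampler("volumes must be nonnegative and concentrations positive",
                     "design_error")
  }
  v_ul <- volume_nl / 1000
  stock_um <- stock_mm * 1000
  denom <- if (exact) prefill_ul + v_ul else prefill_ul
  stock_um * v_ul / denom
}

#' Iterative two-sided Grubbs outlier test
#'
#' Repeatedly computes `G = max |x - mean| / s` and removes the most
#' extreme value whenever `G` exceeds the critical value
#' `((N-1)/sqrt(N)) * sqrt(t^2 / (N-2+t^2))`, with `t` the upper
#' `alpha/(2N)` quantile of the t distribution on `N-2` degrees of
#' freedom, until no further value is removed. With fewer than three
#' values the test is not applicable and the data are returned untouched.
#'
#' @param values numeric vector.
#' @param alpha significance level per iteration (default 0.05).
#' @return a list: `retained`, `removed`, `note` (`"ok"` or
#'   `"test not applicable"`), `n_removed`.
#' @export
grubbs_outliers <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  removed <- numeric(0)
  if (length(values) < 3) {
    return(list(retained = values, removed = removed,
                note = "test not applicable (n < 3)", n_removed = 0L))
  }
  repeat {
    n <- length(values)
    if (n < 3) break
    s <- stats::sd(values)
    if (s == 0) break
    dev <- abs(values - mean(values))
    g <- max(dev) / s
    tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
    g_crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
    if (g > g_crit) {
      idx <- which.max(dev)
      removed <- c(removed, values[idx])
      values <- values[-idx]
    } else {
      break
    }
  }
  list(retained = values, removed = removed, note = "ok",
       n_removed = length(removed))
}

#' Fit the fluorescence standard curve
#'
#' Ordinary least squares of intensity on concentration over the
#' calibration standards, optionally after per-concentration Grubbs
#' screening of replicates (hand pipetting occasionally produces gross
#' errors). The standards' concentrations are treated as error-free;
#' scatter enters only through the fit.
#'
#' @param standards data frame with columns `concentration_um` and
#'   `intensity`.
#' @param apply_grubbs screen replicates per concentration with
#'   [grubbs_outliers()] first?
#' @param alpha Grubbs significance level.
#' @return a `standard_curve`: slope (intensity per uM), intercept,
#'   residual standard deviation, R^2, the retained points and the
#'   underlying `lm` fit. Slope must be positive for a usable curve.
#' @export
fit_standard_curve <- function(standards, apply_grubbs = TRUE, alpha = 0.05) {
  standards <- tibble::as_tibble(standards)
  if (!all(c("concentration_um", "intensity") %in% names(standards))) {
    stop_nanosampler("standards need columns concentration_um and intensity",
                     "curve_error")
  }
  n_outliers <- 0L
  if (apply_grubbs) {
    screened <- standards |>
      dplyr::group_by(.data$concentration_um) |>
      dplyr::group_modify(function(df, key) {
        g <- grubbs_outliers(df$intensity, alpha)
        tibble::tibble(intensity = g$retained)
      }) |>
      dplyr::ungroup()
    n_outliers <- nrow(standards) - nrow(screened)
    standards <- screened
  }
  if (length(unique(standards$concentration_um)) < 2) {
    stop_nanosampler("need at least 2 distinct standard concentrations after screening",
                     "insufficient_data")
  }
  fit <- stats::lm(intensity ~ concentration_um, data = standards)
  co <- stats::coef(fit)
  structure(
    list(
      slope = unname(co["concentration_um"]),
      intercept = unname(co["(Intercept)"]),
      sigma = stats::sigma(fit),
      r_squared = suppressWarnings(summary(fit)$r.squared),
      n_points = nrow(standards),
      n_outliers_removed = n_outliers,
      data = standards,
      fit = fit
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> intensity = %.4g * C + %.4g (n = %d, R^2 = %.5f)\n",
              x$slope, x$intercept, x$n_points, x$r_squared))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x a `standard_curve`.
#' @param ... passed on.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = suppressWarnings(summary(x$fit)$coefficients[, "Std. Error"])
  )
}

#' @rdname fit_standard_curve
#' @param object a `standard_curve`.
#' @export
glance.standard_curve <- function(object, ...) {
  tibble::tibble(
    slope = object$slope,
    intercept = object$intercept,
    sigma = object$sigma,
    r.squared = object$r_squared,
    n_points = object$n_points,
    n_outliers_removed = object$n_outliers_removed
  )
}

#' @rdname fit_standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration_um, y = .data$intensity)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "steelblue") +
    ggplot2::labs(x = "Fluorescein concentration (uM)",
                  y = "Fluorescence intensity (a.u.)",
                  title = "Calibration standard curve") +
    ggplot2::theme_minimal()
}

#' Back-calculate a dispensed volume from a fluorescence reading
#'
#' The measured concentration is read off the standard curve,
#' `C = (I - intercept) / slope`, and inverted through the exact dilution
#' model `C = C_stock * V / (V_prefill + V)`:
#' `V = C * V_prefill / (C_stock - C)`, reported in nL. Readings implying
#' a non-positive concentration, or one at or above the stock
#' concentration (an impossible dilution), are rejected.
#'
#' @param intensity fluorescence reading(s), arbitrary units.
#' @param curve a [fit_standard_curve()] result.
#' @param stock_mm stock concentration of the dispensed fluorescein, mM.
#' @param prefill_ul well prefill volume, uL.
#' @return dispensed volume(s) in nL.
#' @export
estimate_dispensed_volume <- function(intensity, curve, stock_mm, prefill_ul = 20) {
  if (!inherits(curve, "standard_curve")) {
    stop_nanosampler("curve must be a standard_curve", "curve_error")
  }
  if (curve$slope <= 0) {
    stop_nanosampler("standard curve slope must be positive to be usable", "curve_error")
  }
  conc_um <- (intensity - curve$intercept) / curve$slope
  stock_um <- stock_mm * 1000
  # readings indistinguishable from the blank (1e-9 uM ~ 6 orders below the
  # 3-7 uM working range) are rejected as non-positive concentrations
  if (any(conc_um <= 1e-9)) {
    stop_nanosampler("reading at or below the curve intercept implies a non-positive concentration",
                     "estimation_error")
  }
  if (any(conc_um >= stock_um)) {
    stop_nanosampler("measured concentration at or above the stock concentration: impossible dilution",
                     "estimation_error")
  }
  v_ul <- conc_um * prefill_ul / (stock_um - conc_um)
  v_ul * 1000
}

#' Summarize per-group dispensed-volume estimates
#'
#' For each (nominal volume, batch) group: Grubbs screening of the
#' replicate volume estimates, then mean, CV% (100 * sd / mean) and
#' absolute error % versus the nominal volume
#' (100 * |mean - nominal| / nominal). Groups left with fewer than two
#' retained replicates are omitted with a warning (no CV is defined).
#'
#' @param estimates tibble with columns `group`, `nominal_nl`,
#'   `volume_nl` (one row per retained or raw replicate), optionally
#'   `batch`.
#' @param apply_grubbs screen each group with [grubbs_outliers()]?
#' @param alpha Grubbs significance level.
#' @return a `volumetry_summary` tibble ordered by nominal volume:
#'   `group`, `nominal_nl`, `n`, `n_outliers_removed`, `mean_nl`,
#'   `cv_pct`, `abs_error_pct`.
#' @export
summarize_volumetry <- function(estimates, apply_grubbs = TRUE, alpha = 0.05) {
  estimates <- tibble::as_tibble(estimates)
  needed <- c("group", "nominal_nl", "volume_nl")
  if (!all(needed %in% names(estimates))) {
    stop_nanosampler(sprintf("estimates need columns %s", paste(needed, collapse = ", ")),
                     "summary_error")
  }
  out <- estimates |>
    dplyr::group_by(.data$group, .data$nominal_nl) |>
    dplyr::group_modify(function(df, key) {
      vals <- df$volume_nl
      removed <- 0L
      if (apply_grubbs) {
        g <- grubbs_outliers(vals, alpha)
        removed <- g$n_removed
        vals <- g$retained
      }
      if (length(vals) < 2) {
        return(tibble::tibble(n = length(vals), n_outliers_removed = removed,
                              mean_nl = NA_real_, cv_pct = NA_real_,
                              abs_error_pct = NA_real_))
      }
      m <- mean(vals)
      tibble::tibble(
        n = length(vals),
        n_outliers_removed = removed,
        mean_nl = m,
        cv_pct = 100 * stats::sd(vals) / m,
        abs_error_pct = 100 * abs(m - key$nominal_nl) / key$nominal_nl
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$nominal_nl, .data$group)
  dropped <- is.na(out$mean_nl)
  if (any(dropped)) {
    warn_nanosampler(
      sprintf("group(s) %s omitted: fewer than 2 retained replicates",
              paste(out$group[dropped], collapse = ", ")),
      "empty_group"
    )
    out <- out[!dropped, ]
  }
  class(out) <- c("volumetry_summary", class(tibble::tibble()))
  out
}

#' End-to-end analysis of a plate reading
#'
#' Fits the standard curve from the `standard` wells, back-calculates a
#' dispensed volume for every `mixture` well and summarizes per
#' (volume, batch) group. Mixture readings that cannot be inverted
#' (below the intercept or implying an impossible dilution) are dropped
#' with a warning rather than failing the whole analysis.
#'
#' @param reading a plate reading tibble with columns `role`
#'   (`"standard"`/`"mixture"`), `group`, `concentration_um` (standards),
#'   `volume_nl` + `stock_mm` (mixtures, the nominal design point) and
#'   `intensity`. See [read_plate_reading()] and
#'   [generate_synthetic_assay()].
#' @param design the [assay_design()] (for the prefill volume).
#' @param alpha Grubbs significance level used for standards and groups.
#' @return a list with `curve` (the [fit_standard_curve()] result),
#'   `estimates` (per-well volume estimates) and `summary`
#'   (the [summarize_volumetry()] table).
#' @export
analyze_volumetry <- function(reading, design = assay_design(), alpha = 0.05) {
  reading <- tibble::as_tibble(reading)
  curve <- fit_standard_curve(dplyr::filter(reading, .data$role == "standard"),
                              apply_grubbs = TRUE, alpha = alpha)
  mixtures <- dplyr::filter(reading, .data$role == "mixture")
  est_one <- function(intensity, stock_mm) {
    tryCatch(
      estimate_dispensed_volume(intensity, curve, stock_mm, design$prefill_ul),
      nanosampler_error = function(e) NA_real_
    )
  }
  estimates <- mixtures |>
    dplyr::mutate(estimated_nl = purrr::map2_dbl(.data$intensity, .data$stock_mm,
                                                 est_one))
  n_bad <- sum(is.na(estimates$estimated_nl))
  if (n_bad > 0) {
    warn_nanosampler(sprintf("%d mixture reading(s) could not be inverted and were dropped",
                             n_bad), "estimation_dropped")
    estimates <- dplyr::filter(estimates, !is.na(.data$estimated_nl))
  }
  summary <- summarize_volumetry(
    dplyr::transmute(estimates, group = .data$group,
                     nominal_nl = .data$volume_nl,
                     volume_nl = .data$estimated_nl),
    apply_grubbs = TRUE, alpha = alpha
  )
  list(curve = curve, estimates = estimates, summary = summary)
}

#' Generate a synthetic fluorescein assay
#'
#' Forward-simulates the dispense-verification experiment: dispensed
#' volumes follow `V = nominal * (1 + bias) * (1 + e)`,
#' `e ~ N(0, dispense_cv)`; mixture intensities follow the *exact*
#' dilution model `C = stock * V / (prefill + V)` mapped through the
#' linear curve with additive Gaussian read noise; standards follow the
#' curve directly with the same read noise. Gross outliers (a well
#' mis-hit or double-dispensed) replace the dispensed volume with 0.25x
#' or 4x its value at the stated rate and are flagged in the
#' `.true_outlier` column. Fully reproducible given `seed`.
#'
#' @param design an [assay_design()].
#' @param dispense_cv multiplicative volume noise (0.05 = 5% CV).
#' @param dispense_bias relative systematic bias of dispensed volumes.
#' @param curve_slope,curve_intercept true linear response (intensity per
#'   uM; intensity offset).
#' @param intensity_sd additive read noise, intensity units.
#' @param outlier_rate probability a mixture well is a gross outlier.
#' @param batches batch labels; groups are (volume x batch), mirroring
#'   per-batch analysis.
#' @param seed RNG seed.
#' @return a plate-reading tibble with truth columns `.true_volume_nl`
#'   and `.true_outlier` alongside the observable columns used by
#'   [analyze_volumetry()].
#' @export
generate_synthetic_assay <- function(design = assay_design(),
                                     dispense_cv = 0.05,
                                     dispense_bias = 0,
                                     curve_slope = 1000,
                                     curve_intercept = 50,
                                     intensity_sd = 25,
                                     outlier_rate = 0,
                                     batches = "batch1",
                                     seed = 1L) {
  stopifnot(dispense_cv >= 0, intensity_sd >= 0,
            outlier_rate >= 0, outlier_rate <= 1)
  withr::local_seed(seed)
  well_counter <- 0
  next_well <- function(n) {
    idx <- well_counter + seq_len(n)
    well_counter <<- well_counter + n
    # row-major walk over a 384-well footprint
    paste0(LETTERS[((idx - 1) %/% 24) %% 16 + 1], (idx - 1) %% 24 + 1)
  }
  standards <- design$standards |>
    tidyr::uncount(.data$replicates) |>
    dplyr::mutate(
      well = next_well(dplyr::n()),
      role = "standard",
      group = paste0("std_", .data$concentration_um),
      intensity = curve_slope * .data$concentration_um + curve_intercept +
        stats::rnorm(dplyr::n(), 0, intensity_sd),
      volume_nl = NA_real_, stock_mm = NA_real_, batch = NA_character_,
      .true_volume_nl = NA_real_, .true_outlier = FALSE
    )
  mixtures <- tidyr::expand_grid(
    design$dispense_sets, batch = batches
  ) |>
    tidyr::uncount(.data$replicates) |>
    dplyr::mutate(
      true_v = .data$volume_nl * (1 + dispense_bias) *
        (1 + stats::rnorm(dplyr::n(), 0, dispense_cv)),
      is_outlier = stats::runif(dplyr::n()) < outlier_rate,
      true_v = ifelse(.data$is_outlier,
                      .data$true_v * sample(c(0.25, 4), dplyr::n(), replace = TRUE),
                      .data$true_v),
      true_v = pmax(.data$true_v, 0),
      conc_um = .data$stock_mm * 1000 * (.data$true_v / 1000) /
        (design$prefill_ul + .data$true_v / 1000),
      well = next_well(dplyr::n()),
      role = "mixture",
      group = paste0(.data$volume_nl, "nL_", .data$batch),
      intensity = curve_slope * .data$conc_um + curve_intercept +
        stats::rnorm(dplyr::n(), 0, intensity_sd),
      concentration_um = NA_real_,
      .true_volume_nl = .data$true_v,
      .true_outlier = .data$is_outlier
    ) |>
    dplyr::select(-dplyr::all_of(c("true_v", "is_outlier", "conc_um")))
  dplyr::bind_rows(
    dplyr::select(standards, dplyr::all_of(plate_reading_cols())),
    dplyr::select(mixtures, dplyr::all_of(plate_reading_cols()))
  )
}

plate_reading_cols <- function() {
  c("well", "role", "group", "batch", "concentration_um",
    "volume_nl", "stock_mm", "intensity", ".true_volume_nl", ".true_outlier")
}

#' Read and write plate-reader exports
#'
#' CSV with one row per well: `well`, `role` (`standard`/`mixture`),
#' `group`, `batch`, `concentration_um` (standards), `volume_nl` and
#' `stock_mm` (mixtures, the nominal design point) and `intensity`.
#'
#' @param path CSV file path.
#' @return a plate-reading tibble.
#' @export
read_plate_reading <- function(path) {
  reading <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("well", "role", "group", "intensity")
  missing <- setdiff(needed, names(reading))
  if (length(missing) > 0) {
    stop_nanosampler(sprintf("plate reading is missing column(s): %s",
                             paste(missing, collapse = ", ")), "parse_error")
  }
  if (any(reading$intensity < 0, na.rm = TRUE)) {
    stop_nanosampler("fluorescence intensities must be nonnegative", "parse_error")
  }
  reading
}

#' @rdname read_plate_reading
#' @param reading a plate-reading tibble.
#' @export
write_plate_reading <- function(reading, path) {
  readr::write_csv(dplyr::select(reading, -dplyr::starts_with(".")), path)
  invisible(path)
}

#' @rdname summarize_volumetry
#' @param object a `volumetry_summary`.
#' @param ... unused.
#' @export
autoplot.volumetry_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$nominal_nl), y = .data$mean_nl,
                               fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_nl * (1 - .data$cv_pct / 100),
                   ymax = .data$mean_nl * (1 + .data$cv_pct / 100)),
      position = ggplot2::position_dodge(width = 0.8), width = 0.3
    ) +
    ggplot2::labs(x = "Nominal dispensed volume (nL)",
                  y = "Estimated volume (nL)",
                  fill = "Batch",
                  title = "Dispense verification (error bars: +/- CV)") +
    ggplot2::theme_minimal()
}
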