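test_that("every design point targets the same nominal final concentration", {
  vols <- c(500, 100, 50, 20, 10, 5)
  stocks <- c(0.2, 1, 2, 5, 10, 20)
  expect_equal(nominal_final_concentration(vols, stocks, 20), rep(5, 6))
  expect_equal(nominal_final_concentration(0, 1, 20), 0)
  expect_error(nominal_final_concentration(5, -1, 20), class = "nanosampler_design_error")
  # the exact convention differs from the ratio convention by at most 2.5%
  # at the largest design volume (500 nL into 20 uL)
  ratio <- nominal_final_concentration(vols, stocks, 20)
  exact <- nominal_final_concentration(vols, stocks, 20, exact = TRUE)
  gap <- abs(ratio - exact) / ratio
  expect_equal(max(gap), 0.5 / 20.5, tolerance = 1e-9)
  expect_lt(max(gap), 0.025)
})

test_that("Grubbs screening matches a direct critical-value oracle", {
  # independent oracle: one Grubbs iteration from the t-quantile formula
  grubbs_once <- function(x, alpha = 0.05) {
    n <- length(x)
    g <- max(abs(x - mean(x))) / sd(x)
    tq <- qt(1 - alpha / (2 * n), n - 2)
    crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
    list(remove = g > crit, idx = which.max(abs(x - mean(x))))
  }

  expect_equal(grubbs_outliers(c(9, 10, 11))$retained, c(9, 10, 11))

  x <- c(10, 10.1, 9.9, 10.05, 25)
  oracle <- grubbs_once(x)
  expect_true(oracle$remove)
  expect_equal(oracle$idx, 5L)
  res <- grubbs_outliers(x)
  expect_equal(res$removed, 25)
  expect_equal(sort(res$retained), c(9.9, 10, 10.05, 10.1))
  expect_false(grubbs_once(res$retained)$remove)   # iteration stops, same as oracle

  small <- grubbs_outliers(c(1, 2))
  expect_equal(small$retained, c(1, 2))
  expect_match(small$note, "not applicable")

  # alpha -> 0 removes nothing; removals nonincreasing as alpha decreases
  expect_equal(grubbs_outliers(x, alpha = 1e-12)$n_removed, 0L)
  withr::local_seed(19)
  for (i in 1:20) {
    y <- c(rnorm(8), rnorm(2, sd = 8))
    removals <- vapply(c(0.2, 0.1, 0.05, 0.01, 0.001),
                       function(a) grubbs_outliers(y, a)$n_removed, integer(1))
    expect_true(all(diff(removals) <= 0))
  }
})

test_that("standard curves recover exact and noisy linear responses", {
  conc <- rep(3:7, each = 5)
  exact <- tibble::tibble(concentration_um = conc, intensity = 100 * conc + 10)
  fit <- fit_standard_curve(exact)
  expect_equal(fit$slope, 100)
  expect_equal(fit$intercept, 10)
  expect_lt(fit$sigma, 1e-9)

  # duplicated noiseless replicates give the same line as singles
  single <- fit_standard_curve(tibble::tibble(concentration_um = 3:7,
                                              intensity = 100 * (3:7) + 10))
  expect_equal(single$slope, fit$slope)
  expect_equal(single$intercept, fit$intercept)

  # noisy: slope within 3 closed-form OLS standard errors of truth
  withr::local_seed(29)
  sigma <- 40
  noisy <- tibble::tibble(concentration_um = conc,
                          intensity = 100 * conc + 10 + rnorm(length(conc), 0, sigma))
  nf <- fit_standard_curve(noisy, apply_grubbs = FALSE)
  se_slope <- sigma / sqrt(sum((conc - mean(conc))^2))
  expect_lt(abs(nf$slope - 100), 3 * se_slope)

  expect_error(
    fit_standard_curve(tibble::tibble(concentration_um = rep(5, 4),
                                      intensity = rnorm(4))),
    class = "nanosampler_insufficient_data"
  )
})

test_that("volume estimation inverts the exact dilution forward model", {
  curve_exact <- fit_standard_curve(
    tibble::tibble(concentration_um = 3:7, intensity = 100 * (3:7) + 10)
  )
  forward <- function(v_nl, stock_mm, prefill = 20) {
    conc <- stock_mm * 1000 * (v_nl / 1000) / (prefill + v_nl / 1000)
    100 * conc + 10
  }
  expect_equal(
    estimate_dispensed_volume(forward(100, 1), curve_exact, 1, 20), 100,
    tolerance = 1e-9
  )
  # all six design points round-trip noiselessly
  vols <- c(500, 100, 50, 20, 10, 5)
  stocks <- c(0.2, 1, 2, 5, 10, 20)
  est <- mapply(function(v, s)
    estimate_dispensed_volume(forward(v, s), curve_exact, s), vols, stocks)
  expect_equal(unname(est), vols, tolerance = 1e-9)

  expect_error(estimate_dispensed_volume(10, curve_exact, 1),
               class = "nanosampler_estimation_error")  # at the intercept
  expect_error(estimate_dispensed_volume(1e9, curve_exact, 0.001),
               class = "nanosampler_estimation_error")  # impossible dilution
})

test_that("group summaries compute CV and absolute error from the formulas", {
  tab <- summarize_volumetry(tibble::tibble(
    group = rep(c("g1", "g2", "g3"), each = 3),
    nominal_nl = rep(c(50, 50, 50), each = 3),
    volume_nl = c(50, 50, 50, 48, 50, 52, 40, 40, 40)
  ), apply_grubbs = FALSE)
  g1 <- tab[tab$group == "g1", ]
  expect_equal(g1$cv_pct, 0)
  expect_equal(g1$abs_error_pct, 0)
  g2 <- tab[tab$group == "g2", ]
  expect_equal(g2$mean_nl, 50)
  expect_equal(g2$cv_pct, 100 * sd(c(48, 50, 52)) / 50)
  expect_equal(g2$cv_pct, 4, tolerance = 1e-12)
  expect_equal(g2$abs_error_pct, 0)
  g3 <- tab[tab$group == "g3", ]
  expect_equal(g3$abs_error_pct, 20)
  expect_warning(
    summarize_volumetry(tibble::tibble(group = "solo", nominal_nl = 50,
                                       volume_nl = 49)),
    class = "nanosampler_empty_group"
  )
})

test_that("a noiseless synthetic assay is recovered exactly", {
  reading <- generate_synthetic_assay(dispense_cv = 0, dispense_bias = 0,
                                      intensity_sd = 0, outlier_rate = 0, seed = 1)
  res <- analyze_volumetry(reading)
  expect_equal(res$curve$slope, 1000)
  expect_equal(res$curve$intercept, 50)
  expect_equal(res$summary$abs_error_pct, rep(0, nrow(res$summary)),
               tolerance = 1e-9)
  expect_equal(res$summary$cv_pct, rep(0, nrow(res$summary)), tolerance = 1e-9)
  expect_equal(sort(unique(res$summary$nominal_nl)), c(5, 10, 20, 50, 100, 500))
})

test_that("estimated CVs are unbiased at the design settings", {
  # 200 seeds x 5 replicates at 5% dispense CV; loop over seeds and pool
  # per-group CV estimates. Read noise off to isolate the volume CV.
  cvs <- unlist(lapply(1:200, function(s) {
    reading <- generate_synthetic_assay(dispense_cv = 0.05, intensity_sd = 0,
                                        seed = s)
    res <- suppressWarnings(analyze_volumetry(reading))
    res$summary$cv_pct
  }))
  # sd estimates from n=5 have known downward bias c4 = sqrt(2/(n-1)) *
  # gamma(n/2) / gamma((n-1)/2); the pooled mean CV should sit at c4 * 5%
  n <- 5
  c4 <- sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)
  mc_se <- sd(cvs) / sqrt(length(cvs))
  expect_lt(abs(mean(cvs) - c4 * 5), 4 * mc_se + 0.1)
})

test_that("absolute-error estimates center on the injected bias", {
  errs <- unlist(lapply(1:50, function(s) {
    reading <- generate_synthetic_assay(dispense_cv = 0.01, dispense_bias = 0.08,
                                        intensity_sd = 0, seed = 100 + s)
    suppressWarnings(analyze_volumetry(reading))$summary$abs_error_pct
  }))
  expect_equal(mean(errs), 8, tolerance = 0.75)
})

test_that("Grubbs screening catches most injected gross outliers", {
  caught <- total <- 0
  for (s in 1:40) {
    reading <- generate_synthetic_assay(dispense_cv = 0.02, intensity_sd = 0,
                                        outlier_rate = 0.2, seed = 200 + s)
    truth <- reading[reading$role == "mixture", ]
    res <- suppressWarnings(analyze_volumetry(reading))
    total <- total + sum(truth$.true_outlier)
    caught <- caught + sum(res$summary$n_outliers_removed)
  }
  expect_gte(caught, total / 2)
})

test_that("plate readings round-trip through CSV", {
  reading <- generate_synthetic_assay(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_reading(reading, path)
  back <- read_plate_reading(path)
  expect_false(any(startsWith(names(back), ".")))  # truth columns stripped
  expect_equal(nrow(back), nrow(reading))
  expect_equal(back$intensity, reading$intensity, tolerance = 1e-9)
  res <- suppressWarnings(analyze_volumetry(back))
  expect_s3_class(res$summary, "volumetry_summary")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("well,role\nA1,standard", bad)
  expect_error(read_plate_reading(bad), class = "nanosampler_parse_error")
})
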