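test_that("drift correction recovers injected per-gel factors and is idempotent at reference", {
  p <- make_default_panel(10, seed = 1)
  nm <- quiet_noise()
  tab <- replicate_table(p, 1500, 2, nm, seed = 2)
  spikes <- panel_spikes(p, nm, tab)

  # spikes at reference: factor 1, table unchanged
  corr <- drift_correction(tab, spikes)
  expect_equal(unname(attr(corr, "drift_factors")), 1, tolerance = 1e-10)
  expect_equal(corr$intensity, tab$intensity, tolerance = 1e-10)

  # inject a known drift factor and recover it through the spikes
  nmn <- noise_model(cv_intraday_raw = 0.058, capture_bias_cv = 0,
                     scanner_drift_sd = 0)
  tab2 <- replicate_table(p, 1500, 4, nmn, seed = 3)
  tab2$intensity <- tab2$intensity * 0.8
  spikes2 <- panel_spikes(p, nmn, tab2)
  corr2 <- drift_correction(tab2, spikes2)
  spike_se <- nmn$cv_intraday_raw / sqrt(nrow(spikes2) * 4)
  expect_lt(abs(attr(corr2, "drift_factors")[[1]] - 0.8), 3 * 0.8 * spike_se)

  # corrected replicate spread across gels is tighter than raw
  nm3 <- noise_model(scanner_drift_sd = 0.2, capture_bias_cv = 0)
  gels <- paste0("gel", 1:8)
  tabs <- lapply(seq_along(gels), function(i)
    replicate_table(p, 1500, 1, nm3, seed = 10 + i, gel_id = gels[i]))
  tab3 <- do.call(rbind, tabs)
  class(tab3) <- c("intensity_table", "data.frame")
  spikes3 <- panel_spikes(p, nm3, tabs[[1]])
  corr3 <- drift_correction(tab3, spikes3)
  raw_cv <- cv_summary(tab3, "interday")$mean_cv
  cor_cv <- cv_summary(corr3, "interday")$mean_cv
  expect_lt(cor_cv, raw_cv)

  # missing spike-ins on a gel is an error naming the gel
  no_spikes <- tab[!tab$mirna_id %in% spikes$mirna_id, ]
  expect_error(drift_correction(no_spikes, spikes), "gel1")
})

test_that("standard curves fit proportional data exactly and refuse saturation", {
  sc <- fit_standard_curve(c(15, 150, 1500, 15000),
                           43 * c(15, 150, 1500, 15000), "m")
  expect_equal(sc$slope, 1, tolerance = 1e-12)
  expect_equal(sc$intercept, log10(43), tolerance = 1e-12)
  expect_equal(sc$r_squared, 1)

  sc2 <- fit_standard_curve(c(10, 1000), c(500, 50000), "m")
  expect_equal(sc2$r_squared, 1)
  expect_equal(intensity_to_amount(500, sc2)$amount, 10, tolerance = 1e-10)

  expect_error(fit_standard_curve(c(1, 10), c(1, 10), saturated = c(FALSE, TRUE)),
               "saturat")
  expect_error(fit_standard_curve(1, 1), ">= 2")
  expect_error(fit_standard_curve(c(0, 1), c(1, 2)), "> 0")
})

test_that("noisy 4-point curves stay near slope 1 with high r-squared", {
  ok <- vapply(1:60, function(s) {
    std_am <- c(15, 150, 1500, 15000)
    p <- flat_panel("m")
    nm <- noise_model(cv_intraday_raw = 0.058, capture_bias_cv = 0,
                      scanner_drift_sd = 0)
    std <- simulate_intensities(
      matrix(std_am, nrow = 1, ncol = 4, dimnames = list("m", NULL)), p, nm,
      sample_sheet(paste0("s", 1:4)), seed = s)
    sc <- fit_standard_curve(std_am, std$intensity, "m")
    sc$slope > 0.9 && sc$slope < 1.1 && sc$r_squared > 0.98
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("curve inversion is monotone, flags range violations, maps zero to zero", {
  sc <- fit_standard_curve(c(10, 100, 1000, 10000),
                           5 * c(10, 100, 1000, 10000)^0.97, "m")
  at0 <- intensity_to_amount(0, sc)
  expect_equal(at0$amount, 0)
  expect_equal(at0$flags, "below_range")

  xs <- 10^seq(log10(50), log10(35000), length.out = 25)
  inv <- intensity_to_amount(xs, sc)
  expect_true(all(diff(inv$amount) > 0))
  expect_true(all(inv$flags == "."))

  tiny <- intensity_to_amount(1e-3, sc)            # below the curve range
  expect_true(is.na(tiny$amount))
  expect_equal(tiny$flags, "extrapolated")
  tiny2 <- intensity_to_amount(1e-3, sc, extrapolate = TRUE)
  expect_false(is.na(tiny2$amount))
  expect_equal(tiny2$flags, "extrapolated")
  expect_error(intensity_to_amount(-1, sc), "domain")
})

test_that("median inversion error on noisy unknowns across 3 decades is < 15%", {
  p <- flat_panel("m")
  nm <- noise_model(cv_intraday_raw = 0.058, capture_bias_cv = 0,
                    scanner_drift_sd = 0)
  curves <- panel_curves(p, "m", noise = nm, seed = 50)
  truth <- 10^stats::runif(40, log10(20), log10(12000))
  tab <- simulate_intensities(
    matrix(truth, nrow = 1, dimnames = list("m", NULL)), p, nm,
    sample_sheet(paste0("u", seq_along(truth))), seed = 51)
  est <- intensity_to_amount(tab$intensity, curves[["m"]],
                             extrapolate = TRUE)$amount
  expect_lt(stats::median(abs(est / truth - 1)), 0.15)
})

test_that("inhibition correction inverts the simulator exactly and stays unbiased with noise", {
  crv <- inhibition_curve("miR-21-5p")
  amol <- c(0, 10, 500, 1500)
  for (bg in c(0, 250, 500)) {
    eff <- simulate_inhibition_curve(bg, crv)
    expect_equal(correct_inhibition(amol * eff, bg, crv), amol,
                 tolerance = 1e-12)
  }
  expect_equal(correct_inhibition(100, 0, crv), 100)

  # noisy end-to-end at 500 ng background: bias < 5%
  p <- flat_panel("miR-21-5p")
  nm <- noise_model(cv_intraday_raw = 0.058, capture_bias_cv = 0,
                    scanner_drift_sd = 0)
  n <- 200
  sheet <- sample_sheet(paste0("r", 1:n), input_type = "total_rna_ng",
                        input_amount = 500)
  tab <- simulate_intensities(
    matrix(1500, nrow = 1, ncol = n,
           dimnames = list("miR-21-5p", paste0("r", 1:n))),
    p, nm, sheet, seed = 13)
  curves <- panel_curves(p, "miR-21-5p", noise = nm, seed = 60)
  est <- intensity_to_amount(tab$intensity, curves[[1]],
                             extrapolate = TRUE)$amount
  corrected <- correct_inhibition(est, 500, crv)
  expect_lt(abs(mean(corrected) / 1500 - 1), 0.05)
})

test_that("unit conversions match Avogadro arithmetic and the 15 pg/cell convention", {
  expect_equal(round(amol_to_copies(1)), 602214)
  expect_equal(amol_to_copies(0), 0)
  expect_equal(amol_to_copies(1000), 6.02214076e8)
  expect_error(amol_to_copies(-1), "domain")

  expect_equal(cell_equivalents("cells", 10000), 10000)
  expect_equal(round(cell_equivalents("total_rna_ng", 500)), 33333)
  expect_equal(cell_equivalents("total_rna_ng", 75), 5000)
  expect_error(cell_equivalents("bogus", 1), "input_type")
  expect_error(cell_equivalents("cells", 0), "domain")
})

test_that("noise-free pipeline is the identity on copies per cell", {
  p <- make_default_panel(10, seed = 2)
  nm <- quiet_noise()
  ids <- panel_targets(p, c("target", "reference"))
  true_cpc <- stats::setNames(c(15, 150, 1500, 15000, 150000,
                                147056)[seq_along(ids)], ids)
  cells <- 10000
  amol <- true_cpc * cells / 6.02214076e5
  tab <- simulate_intensities(matrix(amol, ncol = 1,
                                     dimnames = list(ids, "A")),
                              p, nm, sample_sheet("A"), seed = 5)
  curves <- panel_curves(p, noise = nm, seed = 70,
                         std_amounts = c(0.1, 10, 1000, 100000))
  spikes <- panel_spikes(p, nm, tab)
  sheet <- sample_sheet("A", input_type = "cells", input_amount = cells)
  prof <- compute_copy_profile(tab, spikes, curves, sheet)
  cmp <- merge(data.frame(mirna_id = ids, true = true_cpc),
               as.data.frame(prof))
  expect_equal(cmp$copies_per_cell, cmp$true, tolerance = 1e-9)
  # the full reported range is representable without over/underflow
  expect_true(all(is.finite(cmp$copies_per_cell)))
  expect_error(compute_copy_profile(tab, spikes, curves[-1], sheet),
               "calibration error")
})

test_that("copy-number output is invariant to a per-gel intensity rescaling", {
  p <- make_default_panel(10, seed = 2)
  nm <- quiet_noise()
  ids <- panel_targets(p, c("target", "reference"))
  amol <- stats::setNames(rep(100, length(ids)), ids)
  tab <- simulate_intensities(matrix(amol, ncol = 1,
                                     dimnames = list(ids, "A")),
                              p, nm, sample_sheet("A"), seed = 6)
  curves <- panel_curves(p, noise = nm, seed = 80)
  spikes <- panel_spikes(p, nm, tab)
  sheet <- sample_sheet("A", input_type = "cells", input_amount = 5000)
  prof1 <- compute_copy_profile(tab, spikes, curves, sheet)
  tab2 <- tab
  tab2$intensity <- tab2$intensity * 3.7
  prof2 <- compute_copy_profile(tab2, spikes, curves, sheet)
  expect_equal(prof2$copies_per_cell, prof1$copies_per_cell,
               tolerance = 1e-9)
})

test_that("replicate copy-number CV reflects band noise plus calibration variance", {
  p <- make_default_panel(12, seed = 3)
  ids <- panel_targets(p, c("target", "reference"))
  nm <- noise_model(cv_intraday_raw = 0.12, capture_bias_cv = 0,
                    scanner_drift_sd = 0.2)
  amol <- stats::setNames(rep(500, length(ids)), ids)
  gels <- paste0("g", 1:4)
  tabs <- lapply(1:4, function(i) {
    sheet <- sample_sheet("A", gel_id = gels[i], replicate_id = i)
    t <- simulate_intensities(matrix(amol, ncol = 1,
                                     dimnames = list(ids, "A")),
                              p, nm, sheet, seed = 100 + i)
    t$intensity <- t$intensity *
      stats::rlnorm(1, -0.5 * log(1 + 0.12^2), sqrt(log(1 + 0.12^2)))
    t
  })
  tab <- do.call(rbind, tabs)
  class(tab) <- c("intensity_table", "data.frame")
  spikes <- panel_spikes(p, quiet_noise(), tabs[[1]])
  curves <- panel_curves(p, noise = quiet_noise(), seed = 90)
  sheet <- sample_sheet("A", input_type = "cells", input_amount = 5000)
  prof <- compute_copy_profile(tab, spikes, curves, sheet)
  mean_cv <- mean(prof$cv, na.rm = TRUE)
  # 12% per-band noise plus ~6% spike-correction noise, estimated from
  # only 4 replicates: tens of percent, never collapsed to zero
  expect_gt(mean_cv, 0.05)
  expect_lt(mean_cv, 0.45)
})
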