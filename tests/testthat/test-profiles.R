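test_that("normalization schemes satisfy their defining identities", {
  p <- make_default_panel(10, seed = 1)
  ids <- p$mirna_id
  set.seed(4)
  v <- stats::setNames(stats::runif(length(ids), 10, 1000), ids)

  ref <- normalize_profile(v, p, "reference_gene", ref_id = "RNU44")
  expect_equal(ref$value[ref$mirna_id == "RNU44"], 1)

  fr <- normalize_profile(v, p, "fractional")
  targets <- panel_targets(p, "target")
  expect_equal(sum(fr$value[fr$mirna_id %in% targets]), 1, tolerance = 1e-12)

  # fractional and reference schemes are invariant to global scaling
  fr2 <- normalize_profile(v * 7.3, p, "fractional")
  expect_equal(fr2$value, fr$value, tolerance = 1e-12)
  ref2 <- normalize_profile(v * 7.3, p, "reference_gene", ref_id = "RNU44")
  expect_equal(ref2$value, ref$value, tolerance = 1e-12)

  raw <- normalize_profile(v, p, "raw")
  expect_equal(raw$value, unname(v))

  expect_error(normalize_profile(v, p, "reference_gene", ref_id = "nope"),
               "normalization error")
  v0 <- v; v0[["RNU44"]] <- 0
  expect_error(normalize_profile(v0, p, "reference_gene", ref_id = "RNU44"),
               "zero")
})

test_that("reference normalization collapses constant-RNA and constant-cell designs", {
  # same biology, global input-scale factor between experimental designs:
  # reference normalization must remove it exactly modulo measurement noise
  p <- make_default_panel(12, seed = 2)
  ids <- p$mirna_id
  nm <- noise_model(cv_intraday_raw = 0.058, capture_bias_cv = 0,
                    scanner_drift_sd = 0)
  base <- stats::setNames(10^stats::runif(length(ids), 1, 3), ids)
  amt <- cbind(cellin = base, rnain = base * 0.4)   # 2.5x less input RNA
  tab <- simulate_intensities(amt, p, nm, sample_sheet(colnames(amt)),
                              seed = 21)
  val <- function(s) {
    sub <- tab[tab$sample_id == s, ]
    stats::setNames(sub$intensity, sub$mirna_id)
  }
  n1 <- normalize_profile(val("cellin"), p, "reference_gene", "RNU44")
  n2 <- normalize_profile(val("rnain"), p, "reference_gene", "RNU44")
  m <- merge(as.data.frame(n1), as.data.frame(n2), by = "mirna_id")
  # collapse: agreement up to measurement noise (a few CVs), no 2.5x offset
  expect_lt(stats::median(abs(m$value.x / m$value.y - 1)), 3 * 0.058 * sqrt(2))
  expect_lt(abs(stats::median(m$value.x / m$value.y) - 1), 0.1)
})

test_that("differential ratios and fractional absolute differences behave as defined", {
  p <- flat_panel(c("a", "b", "c"))
  v1 <- c(a = 10, b = 100, c = 890)
  same <- differential(normalize_profile(v1, p, "raw"),
                       normalize_profile(v1, p, "raw"))
  expect_equal(same$ratio, rep(1, 3))

  # 0.1% -> 1% vs 1% -> 10%: equal ratios, unequal absolute differences
  base <- c(a = 0.1, b = 1, c = 98.9)
  trt <- c(a = 1, b = 10, c = 89)
  d <- differential(normalize_profile(trt / sum(trt), p, "fractional"),
                    normalize_profile(base / sum(base), p, "fractional"))
  expect_equal(d$ratio[d$mirna_id == "a"], 10, tolerance = 1e-12)
  expect_equal(d$ratio[d$mirna_id == "b"], 10, tolerance = 1e-12)
  expect_equal(d$abs_diff[d$mirna_id == "a"], 0.009, tolerance = 1e-12)
  expect_equal(d$abs_diff[d$mirna_id == "b"], 0.09, tolerance = 1e-12)
  expect_equal(sum(d$abs_diff), 0, tolerance = 1e-12)

  # scale invariance of ratios
  d2 <- differential(normalize_profile(2 * trt, p, "raw"),
                     normalize_profile(2 * base, p, "raw"))
  d1 <- differential(normalize_profile(trt, p, "raw"),
                     normalize_profile(base, p, "raw"))
  expect_equal(d2$ratio, d1$ratio)

  # zero baseline with signal: undefined, flagged, not infinite
  vb <- c(a = 0, b = 5, c = 5)
  vs <- c(a = 3, b = 5, c = 5)
  du <- differential(normalize_profile(vs, p, "raw"),
                     normalize_profile(vb, p, "raw"))
  expect_true(is.na(du$ratio[du$mirna_id == "a"]))
  expect_equal(du$flags[du$mirna_id == "a"], "undefined_ratio")

  expect_error(differential(normalize_profile(v1, p, "raw"),
                            normalize_profile(v1, p, "fractional")),
               "scheme mismatch")
})

test_that("differential and reference normalization commute on ratios", {
  p <- make_default_panel(8, seed = 3)
  ids <- p$mirna_id
  set.seed(9)
  v1 <- stats::setNames(stats::runif(8, 10, 1000), ids)
  v2 <- stats::setNames(stats::runif(8, 10, 1000), ids)
  # normalize then differential
  r1 <- differential(normalize_profile(v2, p, "reference_gene", "RNU44"),
                     normalize_profile(v1, p, "reference_gene", "RNU44"))
  # differential then normalize the ratios by the reference's ratio
  raw <- differential(normalize_profile(v2, p, "raw"),
                      normalize_profile(v1, p, "raw"))
  r2 <- raw$ratio / raw$ratio[raw$mirna_id == "RNU44"]
  expect_equal(r1$ratio, r2, tolerance = 1e-12)
})

test_that("titration ordering is exact without noise and >= 80% at assay CVs", {
  p <- make_default_panel(26, seed = 1)
  design <- titration_design()
  truth <- titration_truth(p, design)
  amounts <- make_titration_samples(design, truth$s1, truth$s2)

  # noise-free: every species passes exactly
  tab0 <- simulate_intensities(amounts, p, quiet_noise(),
                               sample_sheet(colnames(amounts)), seed = 1)
  res0 <- titration_order_check(tab0, panel = p)
  expect_equal(res0$fraction_correct, 1)

  # duplicates at the assay intraday CV, one gel: near the 19/22 outcome
  nm <- noise_model(cv_intraday_raw = 0.079, capture_bias_cv = 0.10,
                    scanner_drift_sd = 0)
  dup <- amounts[, rep(colnames(amounts), each = 2)]
  sheet <- sample_sheet(colnames(dup), replicate_id = rep(1:2, 4))
  tab <- simulate_intensities(dup, p, nm, sheet, seed = 17)
  res <- titration_order_check(tab, panel = p)
  expect_gte(res$fraction_correct, 0.80)

  # ties fail the strict chain
  tie <- intensity_table("g", 1L, rep(c("S1", "S4", "S3", "S2"), 1),
                         "m", c(1, 2, 2, 3))
  res_tie <- titration_order_check(tie)
  expect_false(res_tie$per_mirna$pass)
  expect_error(titration_order_check(tab0[tab0$sample_id != "S3", ]),
               "missing")
})

test_that("cross-talk matrices recover planted leakage exactly", {
  ids <- paste0("let-7", c("a", "b", "c", "d", "e", "f", "g", "i"))
  p <- flat_panel(ids)
  ct <- crosstalk_preset_let7()

  sim_single <- function(id, leak = NULL) {
    amt <- stats::setNames(as.numeric(ids == id) * 1500, ids)
    simulate_intensities(amt, p, quiet_noise(), crosstalk = leak, seed = 2)
  }

  # leakage-free: identity (diagonal 100%, off-diagonal 0)
  tabs0 <- lapply(ids, sim_single)
  names(tabs0) <- ids
  m0 <- crosstalk_matrix(tabs0, p)
  expect_equal(unname(diag(m0)), rep(100, 8))
  expect_true(all(m0[upper.tri(m0) | lower.tri(m0)] == 0))

  # let-7-like preset: exactly the 5 planted >5% probe:miRNA combinations
  tabs <- lapply(ids, sim_single, leak = ct)
  names(tabs) <- ids
  m <- crosstalk_matrix(tabs, p)
  expect_true(all(m >= 0))
  off <- m
  diag(off) <- 0
  hits <- which(off > 5, arr.ind = TRUE)
  expect_equal(nrow(hits), 5L)
  planted <- rbind(c("let-7a", "let-7f"), c("let-7b", "let-7c"),
                   c("let-7c", "let-7a"), c("let-7d", "let-7a"),
                   c("let-7e", "let-7a"))
  found <- cbind(ids[hits[, 1]], ids[hits[, 2]])
  expect_setequal(paste(found[, 1], found[, 2]),
                  paste(planted[, 1], planted[, 2]))

  # zero on-target input gives a flagged, undefined row
  tabs_bad <- tabs0
  tabs_bad[["let-7a"]]$intensity <- 0
  m_bad <- crosstalk_matrix(tabs_bad, p)
  expect_true("let-7a" %in% attr(m_bad, "flagged"))
  expect_true(all(is.na(m_bad["let-7a", ])))
})

test_that("reference-normalized and copy-scale differential directions agree", {
  # two samples with true fold changes >= 1.5 in both directions; ratios on
  # the reference-normalized intensity scale and on the true-amount scale
  # must agree in sign of log-ratio for nearly all species
  p <- make_default_panel(20, seed = 5)
  ids <- panel_targets(p, c("target", "reference"))
  set.seed(31)
  base <- stats::setNames(10^stats::runif(length(ids), 1.5, 3), ids)
  fold <- stats::setNames(sample(c(1 / 3, 1 / 2, 1 / 1.5, 1.5, 2, 3),
                                 length(ids), replace = TRUE), ids)
  fold[["RNU44"]] <- 1
  trt <- base * fold
  nm <- noise_model(cv_intraday_raw = 0.058, capture_bias_cv = 0.1,
                    scanner_drift_sd = 0)
  amt <- cbind(G0 = base, G1 = trt)[ids, ]
  reps <- amt[, rep(1:2, each = 4)]
  sheet <- sample_sheet(colnames(reps), replicate_id = rep(1:4, 2))
  tab <- simulate_intensities(reps, p, nm, sheet, seed = 32)
  mval <- function(s) {
    sub <- tab[tab$sample_id == s, ]
    tapply(sub$intensity, sub$mirna_id, mean)[ids]
  }
  dref <- differential(normalize_profile(mval("G1"), p, "reference_gene",
                                         "RNU44"),
                       normalize_profile(mval("G0"), p, "reference_gene",
                                         "RNU44"))
  true_ratio <- fold[dref$mirna_id]
  sel <- abs(log(true_ratio)) >= log(1.5)
  agree <- sign(log(dref$ratio[sel])) == sign(log(true_ratio[sel]))
  expect_gte(mean(agree), 0.95)
})
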